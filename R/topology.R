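#' Residue topology of a C-alpha model
#'
#' A topology is the frame-independent skeleton every per-residue statistic
#' indexes into: an ordered table with one C-alpha per residue, identified by
#' chain ID and residue number. Residue order is fixed; every trajectory bound
#' to a topology stores its coordinates in exactly this order.
#'
#' @param chain character vector of chain identifiers.
#' @param resno integer vector of residue numbers (PDB numbering, may be
#'   negative).
#' @param resname character vector of 3-letter residue codes. Defaults to
#'   `"ALA"` for synthetic models.
#' @return An object of class `"topology"`: a data frame with columns
#'   `chain`, `resno`, `resname`, plus a `chain_offsets` attribute mapping each
#'   chain to its (contiguous) index range.
#' @details Invariants enforced at construction: `(chain, resno)` pairs are
#'   unique, and every chain's residues occupy one contiguous block of the
#'   ordered list.
#' @export
topology <- function(chain, resno, resname = NULL) {
  n <- length(chain)
  if (n == 0L) stop("topology must contain at least one residue")
  if (length(resno) != n) stop("'chain' and 'resno' lengths differ")
  if (is.null(resname)) resname <- rep("ALA", n)
  if (length(resname) != n) stop("'resname' length differs from 'chain'")
  chain <- as.character(chain)
  resno <- as.integer(resno)
  key <- paste(chain, resno, sep = ":")
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue number) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  # each chain must be one contiguous run
  runs <- rle(chain)
  if (anyDuplicated(runs$values)) {
    stop("chain(s) ", paste(unique(runs$values[duplicated(runs$values)]),
                            collapse = ", "),
         " occupy non-contiguous index ranges")
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  offsets <- data.frame(chain = runs$values, start = starts, end = ends,
                        stringsAsFactors = FALSE)
  out <- data.frame(chain = chain, resno = resno,
                    resname = as.character(resname),
                    stringsAsFactors = FALSE)
  attr(out, "chain_offsets") <- offsets
  class(out) <- c("topology", "data.frame")
  out
}

#' @export
print.topology <- function(x, ...) {
  off <- chain_offsets(x)
  cat(sprintf("C-alpha topology: %d residues, %d chain(s)\n", nrow(x),
              nrow(off)))
  for (i in seq_len(nrow(off))) {
    cat(sprintf("  chain %s: residues %d..%d (indices %d..%d)\n",
                off$chain[i], x$resno[off$start[i]], x$resno[off$end[i]],
                off$start[i], off$end[i]))
  }
  invisible(x)
}

#' Chain index ranges of a topology
#'
#' @param top a [topology()].
#' @return data frame with columns `chain`, `start`, `end` (1-based indices
#'   into the residue list).
#' @export
chain_offsets <- function(top) {
  stopifnot(inherits(top, "topology"))
  attr(top, "chain_offsets")
}

#' Residue labels ("chain:resno")
#'
#' @param top a [topology()].
#' @return character vector, one `"chain:resno"` label per residue, used as
#'   row/column labels in every result written by the package.
#' @export
residue_labels <- function(top) {
  stopifnot(inherits(top, "topology"))
  paste(top$chain, top$resno, sep = ":")
}

#' Select residues from a topology
#'
#' Builds a selection mask: a sorted, duplicate-free vector of indices into
#' the topology's residue list. Selections drive which residues are fitted,
#' measured, or excluded by the analysis functions (e.g. "align on this chain
#' only").
#'
#' @param top a [topology()].
#' @param chain optional chain ID(s); all residues of those chains.
#' @param resno optional residue numbers (combined with `chain` if both
#'   given; a numeric range can be written `27:42`).
#' @param index optional explicit indices into the residue list.
#' @param invert if `TRUE`, return the complement of the selection.
#' @return integer vector of class `"selection"` (sorted, unique).
#' @export
select_residues <- function(top, chain = NULL, resno = NULL, index = NULL,
                            invert = FALSE) {
  stopifnot(inherits(top, "topology"))
  n <- nrow(top)
  if (is.null(chain) && is.null(resno) && is.null(index)) {
    idx <- seq_len(n)
  } else {
    keep <- rep(TRUE, n)
    if (!is.null(chain)) keep <- keep & top$chain %in% as.character(chain)
    if (!is.null(resno)) keep <- keep & top$resno %in% as.integer(resno)
    idx <- which(keep)
    if (!is.null(index)) {
      index <- as.integer(index)
      if (any(index < 1L | index > n)) {
        stop("selection index out of range 1..", n)
      }
      idx <- if (is.null(chain) && is.null(resno)) index else
        union(idx, index)
    }
  }
  if (invert) idx <- setdiff(seq_len(n), idx)
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0L) stop("selection matches no residues")
  structure(idx, class = "selection")
}

# validate an externally supplied mask against a topology
as_selection <- function(mask, top) {
  if (is.null(mask)) return(select_residues(top))
  idx <- sort(unique(as.integer(mask)))
  if (length(idx) == 0L) stop("empty selection")
  if (any(idx < 1L) || any(idx > nrow(top))) {
    stop("selection indices out of range for this topology")
  }
  structure(idx, class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("residue selection: %d residue(s)\n", length(x)))
  print(unclass(x))
  invisible(x)
}
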