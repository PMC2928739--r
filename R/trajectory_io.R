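# Reading and writing structures, trajectories and result tables.
#
# PDB parsing is delegated to bio3d; this module implements the package's
# residue-resolution policy on top of bio3d's atom table: one C-alpha per
# residue, altloc resolved by occupancy, insertion codes rejected.

# Resolve a bio3d atom table to one CA row per (chain, resno).
# Returns the row indices (into 'atom') of the retained CA records.
resolve_calpha <- function(atom, warn_missing = TRUE) {
  ca <- which(atom$type == "ATOM" & atom$elety == "CA")
  if (length(ca) == 0L) stop("no C-alpha (CA) atoms found")
  if (any(!is.na(atom$insert[ca]) & atom$insert[ca] != "")) {
    bad <- ca[!is.na(atom$insert[ca]) & atom$insert[ca] != ""]
    stop("insertion codes are not supported (first offending residue: ",
         atom$chain[bad[1]], ":", atom$resno[bad[1]], atom$insert[bad[1]], ")")
  }
  key <- paste(atom$chain[ca], atom$resno[ca], sep = ":")
  keep <- integer(0)
  for (k in unique(key)) {
    rows <- ca[key == k]
    if (length(rows) > 1L) {
      alt <- atom$alt[rows]
      occ <- atom$o[rows]
      occ[is.na(occ)] <- 1
      if (all(is.na(alt) | alt == "")) {
        stop("duplicate (chain, residue number) after altloc resolution: ", k)
      }
      # highest occupancy, then first listed
      rows <- rows[order(-occ, seq_along(rows))][1]
    }
    keep <- c(keep, rows)
  }
  # residues present in the file but with no CA record
  if (warn_missing) {
    allkey <- unique(paste(atom$chain[atom$type == "ATOM"],
                           atom$resno[atom$type == "ATOM"], sep = ":"))
    missing <- setdiff(allkey, unique(key))
    if (length(missing) > 0L) {
      warning(length(missing), " residue(s) lack a CA record and were ",
              "skipped: ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  keep
}

#' Read a reference structure from a PDB file
#'
#' Reads a single-model PDB and reduces it to one C-alpha per residue. Chains
#' are detected from the chain-ID column; alternate locations are resolved to
#' the highest-occupancy (then first-listed) conformer; residues without a CA
#' record are skipped with a warning; insertion codes are a hard error.
#'
#' @param path PDB file path.
#' @return list with elements `topology` (a [topology()]) and `coords`
#'   (`residues x 3` matrix, Angstrom), in file order.
#' @export
read_reference_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  rows <- resolve_calpha(pdb$atom)
  if (length(rows) == 0L) stop("no residues parsed from ", path)
  at <- pdb$atom[rows, , drop = FALSE]
  ch <- at$chain
  ch[is.na(ch) | ch == ""] <- "A"
  top <- topology(ch, at$resno, at$resid)
  coords <- as.matrix(at[, c("x", "y", "z")])
  dimnames(coords) <- list(residue_labels(top), c("x", "y", "z"))
  list(topology = top, coords = coords)
}

#' Read a trajectory
#'
#' Reads a multi-model PDB (MODEL/ENDMDL blocks) or the package's plain-text
#' frame-table format (see [write_frame_table()]). Frames may be decimated by
#' `stride`; frame times are `original frame index * frame_interval` so that
#' striding preserves the time axis.
#'
#' @param path file path; format detected from content (`.pdb`/PDB records vs
#'   delimited frame table).
#' @param top optional [topology()] the frames must resolve; derived from the
#'   file when `NULL`.
#' @param stride positive integer decimation factor.
#' @param frame_interval time between successive stored frames, ns (ignored
#'   for frame tables, which carry an explicit time column).
#' @return a [trajectory()] with `equilibration_end = 0` (frame tables written
#'   by this package may carry their own marker, which is restored).
#' @export
read_trajectory <- function(path, top = NULL, stride = 1,
                            frame_interval = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  stride <- as.integer(stride)
  if (stride < 1L) stop("'stride' must be a positive integer")
  head_lines <- readLines(path, n = 5L)
  is_pdb <- grepl("\\.pdb$", path, ignore.case = TRUE) ||
    any(grepl("^(MODEL|ATOM|HETATM|HEADER|REMARK|CRYST1)", head_lines))
  if (is_pdb) {
    read_trajectory_pdb(path, top, stride, frame_interval)
  } else {
    tr <- read_frame_table(path, top)
    if (stride > 1L) tr <- stride_frames(tr, stride) else tr
  }
}

read_trajectory_pdb <- function(path, top, stride, frame_interval) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  rows <- resolve_calpha(pdb$atom)
  at <- pdb$atom[rows, , drop = FALSE]
  ch <- at$chain
  ch[is.na(ch) | ch == ""] <- "A"
  file_top <- topology(ch, at$resno, at$resid)
  if (is.null(top)) {
    top <- file_top
    sel_rows <- rows
  } else {
    want <- residue_labels(top)
    have <- residue_labels(file_top)
    pos <- match(want, have)
    if (anyNA(pos)) {
      stop("trajectory is missing residue(s) required by the topology: ",
           paste(want[is.na(pos)], collapse = ", "))
    }
    sel_rows <- rows[pos]
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  if (nf == 0L) stop("empty trajectory: ", path)
  n <- length(sel_rows)
  coords <- array(0, c(nf, n, 3L))
  coords[, , 1] <- xyz[, 3L * (sel_rows - 1L) + 1L, drop = FALSE]
  coords[, , 2] <- xyz[, 3L * (sel_rows - 1L) + 2L, drop = FALSE]
  coords[, , 3] <- xyz[, 3L * (sel_rows - 1L) + 3L, drop = FALSE]
  bad <- which(apply(coords, 1L, function(f) any(!is.finite(f))))
  if (length(bad) > 0L) {
    f <- bad[1]
    miss <- which(!is.finite(coords[f, , 1]))[1]
    stop("frame ", f, " is missing residue ",
         residue_labels(top)[miss])
  }
  keep <- seq(1L, nf, by = stride)
  trajectory(top, coords[keep, , , drop = FALSE],
             times = (keep - 1L) * frame_interval)
}

#' Write / read the plain-text frame-table trajectory format
#'
#' One row per frame: a `time_ns` column followed by three columns per residue
#' labelled `chain:resno.x|.y|.z` in topology order. Coordinates are written
#' with 17 significant digits so read-back is exact; the equilibration marker
#' is preserved in a header comment.
#'
#' @param traj a [trajectory()].
#' @param path output/input file path.
#' @return `write_frame_table`: the path, invisibly. `read_frame_table`: a
#'   [trajectory()].
#' @export
write_frame_table <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  labs <- residue_labels(traj$topology)
  hdr <- c("time_ns", as.vector(t(outer(labs, c(".x", ".y", ".z"),
                                        paste0))))
  flat <- flatten_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ensdyn frame table",
               sprintf("# equilibration_end_ns: %.17g",
                       traj$equilibration_end),
               paste(hdr, collapse = "\t")), con)
  body <- cbind(traj$times, flat)
  writeLines(apply(body, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_frame_table
#' @param top optional [topology()]; when `NULL` it is rebuilt from the header
#'   labels (residue names default to `ALA`).
#' @export
read_frame_table <- function(path, top = NULL) {
  lines <- readLines(path)
  eq_end <- 0
  eqline <- grep("^# equilibration_end_ns:", lines, value = TRUE)
  if (length(eqline) > 0L) {
    eq_end <- as.numeric(sub("^# equilibration_end_ns:\\s*", "", eqline[1]))
  }
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 2L) stop("empty trajectory: ", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "time_ns" || (length(hdr) - 1L) %% 3L != 0L) {
    stop("malformed frame-table header in ", path)
  }
  labs <- sub("\\.x$", "", hdr[seq(2L, length(hdr), by = 3L)])
  if (is.null(top)) {
    parts <- strsplit(labs, ":", fixed = TRUE)
    top <- topology(vapply(parts, `[`, "", 1L),
                    as.integer(vapply(parts, `[`, "", 2L)))
  } else {
    want <- residue_labels(top)
    if (!identical(labs, want)) {
      miss <- setdiff(want, labs)
      if (length(miss) > 0L) {
        stop("frame 1 is missing residue ", miss[1])
      }
      stop("frame-table residue order differs from the supplied topology")
    }
  }
  vals <- lapply(lines[-1L], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]]))
  nc <- length(hdr)
  if (any(lengths(vals) != nc)) {
    f <- which(lengths(vals) != nc)[1]
    ridx <- (min(lengths(vals)[f], nc - 1L)) %/% 3L + 1L
    stop("frame ", f, " is missing residue ",
         residue_labels(top)[min(ridx, nrow(top))])
  }
  body <- do.call(rbind, vals)
  n <- nrow(top)
  coords <- array(0, c(nrow(body), n, 3L))
  coords[, , 1] <- body[, 1L + seq(1L, 3L * n, by = 3L), drop = FALSE]
  coords[, , 2] <- body[, 1L + seq(2L, 3L * n, by = 3L), drop = FALSE]
  coords[, , 3] <- body[, 1L + seq(3L, 3L * n, by = 3L), drop = FALSE]
  trajectory(top, coords, times = body[, 1L], equilibration_end = eq_end)
}

#' Write a trajectory as a multi-model C-alpha PDB
#'
#' One MODEL/ENDMDL block per frame, one CA ATOM record per residue, in
#' topology order. Used for exporting cluster centroids and medoids.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    cc <- frame_coords(traj, f)
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(top)), top$resname, top$chain, top$resno,
      cc[, 1], cc[, 2], cc[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a labeled result matrix or series to CSV/TSV
#'
#' Matrices are written with `chain:resno` row and column labels; series
#' (vectors or data frames) with their column names. Values are written with 9
#' significant digits, so matrices round-trip to better than 1e-8.
#'
#' @param x numeric matrix (with dimnames), numeric vector, or data frame.
#' @param path output path.
#' @param format `"csv"` or `"tsv"`.
#' @return the path, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  fmt_num <- function(v) {
    if (is.double(v)) sprintf("%.9g", v) else as.character(v)
  }
  if (is.matrix(x)) {
    if (nrow(x) == 0L || ncol(x) == 0L) stop("cannot write an empty matrix")
    if (!all(is.finite(x) | is.na(x))) stop("non-finite values in results")
    df <- data.frame(label = rownames(x) %||% as.character(seq_len(nrow(x))),
                     stringsAsFactors = FALSE)
    body <- apply(x, 2L, fmt_num)
    if (is.null(dim(body))) body <- matrix(body, nrow = nrow(x))
    colnames(body) <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
    out <- cbind(df, body)
  } else if (is.data.frame(x)) {
    if (nrow(x) == 0L) stop("cannot write an empty table")
    out <- x
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) out[[j]] <- sprintf("%.9g", out[[j]])
    }
  } else if (is.numeric(x)) {
    if (length(x) == 0L) stop("cannot write an empty series")
    out <- data.frame(label = names(x) %||% as.character(seq_along(x)),
                      value = fmt_num(as.double(x)),
                      stringsAsFactors = FALSE)
  } else {
    stop("unsupported result type: ", class(x)[1])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write results to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read back a matrix written by [write_results()]
#'
#' @param path input path.
#' @param format `"csv"` or `"tsv"`.
#' @return numeric matrix with the stored row/column labels.
#' @export
read_result_matrix <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
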