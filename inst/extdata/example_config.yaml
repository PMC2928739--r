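# Example ensdyn pipeline configuration.
#
# Runs the full analysis battery on two synthetic trajectories emulating a
# bound (conformationally restricted) and an unbound (mobile) ensemble of a
# two-chain complex, mirroring the analysis layout used for the
# Ubc9-SUMO / Ubc9-SUMO-RanBP2 comparison: chain-pivot RMSD, per-chain msf,
# whole-run and windowed correlation maps, bond-vector autocorrelations,
# joined-ensemble clustering and PCA. Parameter presets for real
# simulations of that system are in sumoylation_presets().
output_dir: ensdyn_example_out
inputs:
  restricted:
    equilibration_end: 0.4
    synthetic:
      generator: gaussian
      chains: {A: 25, B: 20}
      frames: 400
      frame_interval: 0.1
      seed: 101
      variances: 0.16
      blocks:
        - members: [8, 9, 10, 11, 30, 31, 32]
          rho: 0.7
  mobile:
    equilibration_end: 0.5
    synthetic:
      generator: rotation_event
      chains: {A: 25, B: 20}
      frames: 400
      frame_interval: 0.1
      seed: 102
      variances: 0.09
      events:
        - time: 20
          chain: B
          angle: 30
          axis: [0, 0, 1]
          translation: [2, 0, 0]
reference:
  from: restricted
selections:
  chainA: {chain: A}
  chainB: {chain: B}
  motif: {chain: A, resno: [8, 9, 10, 11]}
  contact_loop: {chain: B, resno: [10, 11, 12]}
analyses:
  rmsd:
    - {name: pivotA_measureB, trajectory: mobile, fit: chainA, measure: chainB}
    - {name: selfB, trajectory: mobile, fit: chainB, measure: chainB}
  msf:
    - {name: restricted_A, trajectory: restricted, fit: chainA, measure: chainA}
    - {name: mobile_A, trajectory: mobile, fit: chainA, measure: chainA}
  distance:
    - {name: motif_loop, trajectory: restricted, a: motif, b: contact_loop,
       mode: centroid}
  correlation:
    - {name: restricted, trajectory: restricted, fit: all}
  windowed_correlation:
    - name: halves
      trajectory: restricted
      fit: all
      windows: [[0, 20], [20, 40]]
      block_a: motif
      block_b: contact_loop
  autocorrelation:
    - {name: restricted, trajectory: restricted, delays: [0, 0.4, 1, 5, 20]}
  clustering:
    - name: joined
      trajectories: [restricted, mobile]
      fit: chainA
      selection: chainA
      radius: 1.7
      seed: 1
  pca:
    - name: joined
      trajectories: [restricted, mobile]
      fit: chainA
      selection: chainA
      components: [1, 2]
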