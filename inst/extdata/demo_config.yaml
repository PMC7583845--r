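# Demonstration pipeline configuration: two synthetic trajectories from the
# bundled two-chain scenario, all analysis stages enabled.
seed: 101
scenario: demo
n_trajectories: 2
n_frames: 300
dt_ns: 10

selections:
  plb_all:
    chain: B
    ranges: [[1, 52]]
  plb_nt_bb:
    chain: B
    ranges: [[1, 26]]
    atoms: [N, CA, C, O]
  plb_tm_bb:
    chain: B
    ranges: [[27, 52]]
    atoms: [N, CA, C, O]
  plb_ca:
    chain: B
    ranges: [[1, 52]]
    atoms: [CA]
  tm_core:
    chain: A
    ranges: [[831, 855], [895, 915], [933, 948], [966, 994]]
  tm_core_bb:
    chain: A
    ranges: [[831, 855], [895, 915], [933, 948], [966, 994]]
    atoms: [N, CA, C, O]
  serca_all:
    chain: A
    ranges: [[130, 150], [315, 330], [340, 370], [426, 426],
             [795, 815], [831, 855], [895, 915], [933, 948], [966, 994]]
  ndomain:
    chain: A
    ranges: [[340, 370]]

rmsd:
  - name: plb_nt
    align: plb_tm_bb
    measure: plb_nt_bb
  - name: plb_tm
    align: plb_tm_bb
  - name: serca_tm
    align: tm_core_bb

rmsf:
  align: plb_tm_bb
  target: plb_ca

ss:
  sel: plb_all

occupancy:
  group_a: serca_all
  group_b: plb_all
  cutoff: 3.0

saltbridge:
  p_atom: [B, 16, P]
  partners:
    arg_CZ: [A, 324, CZ]
    lys_NZ: [A, 328, NZ]
  favorable_cutoff: 6.0
  denticity_cutoff: 3.5

hbond:
  donor: [B, 34, ND2]
  h_name: HD2
  acceptor: [A, 801, O]
  d_cutoff: 3.5
  angle_cutoff: 120

motion:
  core: tm_core
  domains:
    N: ndomain

# fixed five-component decomposition (the scenario programs five
# subpopulations); BIC-based selection is available through k_max instead
distfit:
  res_a: [A, 139]
  res_b: [A, 426]
  burn_in_ns: 200
  k: 5
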