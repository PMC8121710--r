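# Reference configuration: every numeric default used by run_pipeline().
# Units: times ps (unless suffixed _ns), distances Angstrom, angles degrees,
# energies kcal/mol.
seed: 1
dt_ps: 10
out_dir: results
stages: [simulate, chi_states, fingerprint, histogram, pca, hbfix]
simulate:
  total_ns: 5000        # observation window per residue (5 us at dt 10 ps)
  n_frames_geom: 60     # frames in the coordinate fixture
chi_states:
  residues: [1, 4, 7, 10, 13, 16]
  min_dwell_ps: 300     # debounce threshold
  syn_window: [-30, 150] # syn chi window; anti is the complement
fingerprint:
  hbond_dist_cutoff: 3.5
  hbond_angle_cutoff: 120
  ion_cutoff: 3.5
  vdw_cutoff: 4.5
histogram:
  bin_width: 0.1
pca:
  stride: 5
  n_components: 10
  selection: backbone
hbfix:
  eta: 1.0
  r_full: 3.0
  r_off: 4.0
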