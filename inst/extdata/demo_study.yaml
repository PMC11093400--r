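# Demo phantom study: two disjoint three-sphere networks on a 24^3 grid,
# localized by a two-condition blocked task; a 0.07% condition effect is
# planted in network A only. Values omitted here fall back to the package
# defaults (see ?demo_study_config).
n_subjects: 12
tr_s: 1.4
baseline: 100
main_response: 1.0
localizer_response: 1.5
amplitude_sd: 0.03
effects:
  network_a: 0.07
  network_b: 0.0
grid:
  shape: [24, 24, 24]
  voxel_size_mm: [2.0, 2.0, 2.0]
networks:
  network_a:
    centers:
      - [7, 7, 7]
      - [7, 17, 7]
      - [17, 7, 7]
    radius_vox: 4
    localizer_condition: taskA
  network_b:
    centers:
      - [7, 7, 18]
      - [7, 17, 18]
      - [17, 7, 18]
    radius_vox: 4
    localizer_condition: taskB
noise:
  white_sd: 1.0
  ar1: 0.3
  drift: 2.0
gss:
  top_fraction: 0.05
  min_subjects: 6
  smoothing_fwhm_mm: 8
  min_mean_parcel_size_vox: 10
  validation_z: 2
  validation_min_cluster_vox: 5
  restrict_to_overlap: true
froi:
  top_fraction: 0.10
  min_voxels: 1
write_bold: false
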