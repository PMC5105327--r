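# Synthetic study emulating the designs of five public human circadian
# expression datasets: three blood studies with dense within-subject
# sampling and two postmortem brain studies with one circadian time per
# subject spread over anatomical areas. Sample and subject counts mirror
# the published designs; the brain organ offset and age phase advance are
# the configured ground truth the pipeline should recover.
organs:
  - organ: blood
    phase_offset: 0.0
  - organ: brain
    phase_offset: 8.5
datasets:
  - dataset_id: blood_a
    organ: blood
    n_subjects: 24
    n_samples: 221
    sampling: dense_within_subject
    age_mean: 27
    age_sd: 5
  - dataset_id: blood_b
    organ: blood
    n_subjects: 22
    n_samples: 147
    sampling: dense_within_subject
    age_mean: 27
    age_sd: 5
  - dataset_id: blood_c
    organ: blood
    n_subjects: 14
    n_samples: 130
    sampling: dense_within_subject
    age_mean: 27
    age_sd: 5
  - dataset_id: brain_a
    organ: brain
    n_subjects: 55
    n_samples: 269
    sampling: one_per_subject
    age_mean: 52
    age_sd: 15
  - dataset_id: brain_b
    organ: brain
    n_subjects: 146
    n_samples: 292
    sampling: one_per_subject
    age_mean: 52
    age_sd: 15
subject_effect_sd: 0.3
subject_scale_sd: 0.1
noise_sd: 1.0
age_phase_advance: 2.0
sex_marker_effect: 5.0
seed: 20160748
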