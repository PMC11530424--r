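[
  {
    "name": "CPU",
    "cores": 480,
    "sample_total_time_s": 79.63,
    "sample_size": 4.0e7,
    "per_task_time_s": 9.550e-4,
    "ref_per_task_time_s": 1.2000e-3
  },
  {
    "name": "MIC",
    "cores": 60,
    "sample_total_time_s": 362.83,
    "sample_size": 4.0e7,
    "per_task_time_s": 5.442e-4,
    "ref_per_task_time_s": 5.9100e-4
  },
  {
    "name": "GPU",
    "cores": 2496,
    "sample_total_time_s": 96.51,
    "sample_size": 4.0e7,
    "per_task_time_s": 2.447e-2,
    "ref_per_task_time_s": 2.6542e-2
  }
]
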