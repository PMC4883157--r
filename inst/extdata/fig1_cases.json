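[
  {"name": "a_always_dominant", "matrix": [[90, 0], [10, 0]], "n_reps": 1, "seed": 0},
  {"name": "b_errors_in_dominant", "matrix": [[80, 10], [0, 10]], "n_reps": 1, "seed": 0},
  {"name": "c_perfect", "matrix": [[90, 0], [0, 10]], "n_reps": 1, "seed": 0},
  {"name": "d_random", "matrix": [[45, 45], [5, 5]], "n_reps": 1, "seed": 0}
]
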