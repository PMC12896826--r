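# Desk-scale smoke configuration: tiny herd, short training, short search.
generator:
  n_per_class: [80, 70, 50, 40]
  scheme: 4
smote:
  k: 5
split:
  ratio: 0.7
train:
  epochs: 3
  batch_size: 64
compress:
  R_target: 0.5
  reward_scale: 0.01
  td3:
    "T": 6
    T1: 4
    "N": 8
    buffer_capacity: 100
finetune:
  epochs: 2
  batch_size: 64
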