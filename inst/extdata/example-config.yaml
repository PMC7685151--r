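# Example configuration for carboniav::run_pipeline().
# A preset names the synthetic generator setup; baseline and detrend
# control the anomaly step. All fields are optional.
preset: two-region   # west-like | east-like | two-region
seed: 7
years: 17
detrend: true
# baseline: [2001, 2017]
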