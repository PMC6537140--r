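# Default acquisition geometry: 80 MHz excitation (12.5 ns period), 4 ns
# gate, 5 prebleach frames at delay 0 followed by 7 FLIM gate delays,
# 336 x 256 px frames at 615 nm projected pixel pitch.
period_ns: 12.5
gate_width_ns: 4.0
delays_ns: [0.0, 1.0, 2.0, 3.0, 4.0, 6.0, 8.0]
n_prebleach: 5
frame_shape: [336, 256]
pixel_size_nm: 615.0
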