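# Example pipeline configuration: every key overrides the package default;
# omitted keys keep their defaults (print them with `ifctrack run --show-config`).
crop_size: 21
frame_buffer_size: 32
response_threshold: 0.06
tracker:
  gate_px: 60
  lateral_weight: 5
  entry_margin_px: 100
  exit_margin_px: 100
  nominal_velocity_px: 40
  max_occlusion_frames: 10
flow:
  flow_rate_ul_per_min: 6
  frame_rate_hz: 500
  shutter_s: 1.0e-4
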