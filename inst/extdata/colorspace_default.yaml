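# Default color-space configuration, spelled out for reference.
# Any key may be omitted; omitted keys fall back to these values
# (axis_scale falls back to gamut calibration against the RGB cube).
rgb_to_xyz: [0.4124564, 0.3575761, 0.1804375,
             0.2126729, 0.7151522, 0.0721750,
             0.0193339, 0.1191920, 0.9503041]
xyz_to_lms: [0.4002, 0.7076, -0.0808,
             -0.2263, 1.1653, 0.0457,
             0.0000, 0.0000, 0.9182]
background_rgb: [0.5, 0.5, 0.5]
axis_sign: [1, 1, -1]
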