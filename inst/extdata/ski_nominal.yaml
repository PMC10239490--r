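# Carving ski, 18 rigid segments joined by revolute bending joints with
# rotational spring-damper elements.  Spring/damper values are
# order-of-magnitude bench estimates (no laboratory identification shipped).
n_segments: 18
length: 1.70
mass: 4.5
width: 0.07
camber_height: 0.004
stiffness: 350.0
damping: 0.6
side_cut_radius: 18.0
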