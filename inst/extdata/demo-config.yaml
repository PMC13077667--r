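# Demo run: simulate baseline acquisitions for every test at a modest
# raster, analyze them, and check recovered deviations against tolerance.
tests: [wedge, output, symmetry, focalspot, vmat-drgs, vmat-leafspeed]
seed: 1
noise_sd: 0.002
tolerance: 2
tolerance_mm: 0.1
npix: 384
pitch: 1
wedge_angle: 30
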