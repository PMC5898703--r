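Package: LightSheetSim
Title: Wave-Optical Simulation of Light-Sheet Microscope Image Formation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scalar wave-optical simulation of image formation in light-sheet
    fluorescence microscopes. A split-step beam-propagation engine with the
    exact (non-paraxial) angular-spectrum propagator advances coherent fields
    through heterogeneous refractive-index volumes; spatially varying detection
    point-spread functions are computed for whole camera planes at once by
    multiplexing non-overlapping point sources in a single propagation; camera
    images arise by spatially varying convolution of the excitation-weighted
    fluorophore density with the tiled PSF set. Includes synthetic phantoms
    (spheres, coated-sphere cell models, a parametric embryo, Perlin-noise
    tissue), adaptive-optics experiments (guide-star phase conjugation,
    shift-shift memory effect, mean-free-path estimation), Zernike aberration
    maps, and independent analytic oracles (Mie partial-wave series, Fresnel
    knife edge, Gaussian beam, direct Rayleigh-Sommerfeld summation) used for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
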