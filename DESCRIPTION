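Package: mbpip
Title: Many-Body Permutationally Invariant Polynomial Potentials with
    Delta Machine Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits, corrects, evaluates and runs dynamics on transferable
    many-body permutationally invariant polynomial (MB-PIP) potentials for
    two-element chain molecules, with linear alkanes C(n)H(2n+2) as the
    reference case.  The total energy is expanded over atom tuples (2-, 3-
    and 4-body), each tuple contribution being a polynomial in Morse
    variables that is exactly invariant under permutations of like atoms.
    All linear coefficients are obtained in a single overdetermined
    least-squares fit to total energies.  A delta-machine-learning layer
    fits a second MB-PIP surface to high-minus-low level energy differences
    and evaluates the stacked potential.  Includes geometry optimisation,
    hairpin-versus-linear conformer gap scans over chain length, NVE
    molecular dynamics with zero-angular-momentum initial conditions, power
    spectra from the velocity autocorrelation function, and a fully
    synthetic two-level alkane test system so the whole pipeline runs
    without any external electronic-structure data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
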