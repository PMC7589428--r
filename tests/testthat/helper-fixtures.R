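# Shared fixtures: all synthetic, built in code at test time.

relErr <- function(x, ref) abs(x - ref) / abs(ref)

# nuclide with a round local energy for hand arithmetic
toyNuclide <- function(E = 1e-12) Radionuclide("toy", halfLife = 100,
                                               localEnergyPerDecay = E)

# small noiseless phantom study, fast enough for every test
smallPhantom <- function(noise = "none", seed = 1L, ...) {
  PhantomSpec(dim = c(32L, 32L, 24L), noise = noise, seed = seed, ...)
}

# single uniform ellipsoid occupying most of a cube, unit density
blobPhantom <- function(n = 48L, semiVox = 11, noise = "none", seed = 1L) {
  PhantomSpec(dim = rep(n, 3L),
              organs = list(phantomOrgan(1L, "blob",
                                         center = rep(n / 2 * 4.42, 3),
                                         semiAxes = rep(semiVox * 4.42, 3),
                                         density_gcc = 1.0,
                                         fractions = 0.02, rates = 0.01)),
              noise = noise, seed = seed)
}

# multiplicative Gaussian noise on a TAC
noisyTac <- function(organ, t, a, A0, sigma) {
  TimeActivityCurve(organ, t, pmax(a * (1 + sigma * stats::rnorm(length(a))),
                                   1e-9), A0)
}

# a FitResult carrying a prescribed TIA (to build TIA maps directly)
fixedTiaFit <- function(organ, tiaVal, A0 = 7200) {
  new("FitResult", organ = organ, model = "monoexp",
      parameters = c(A = 1, lambda = 1), headRule = NA_character_,
      tailRate = NA_real_, tia = tiaVal, tiac = tiaVal / A0, A0 = A0,
      goodness = 1, rss = 0, converged = TRUE, flags = character())
}

patientProtocol <- function() AcquisitionMeta(60, 45)
calibProtocol <- function() AcquisitionMeta(60, 120)
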