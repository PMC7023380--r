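test_that("acquisition arithmetic reproduces the instrument values", {
  p <- devicePreset("UltraShield")
  expect_equal(round(acquisitionTime(p), 2), 7.97)
  pa <- devicePreset("Ascend")
  expect_equal(round(acquisitionTime(pa), 2), 7.97)
  # implied carrier round-trips through the validity invariant
  expect_equal(p@sfo_mhz, 8223.68 / 20.5503)
  expect_true(abs(p@sw_hz - p@sw_ppm * p@sfo_mhz) <= 0.1)
  # trivial case
  expect_equal(acquisitionTime(acquisitionParameters(td = 2, sw_hz = 1,
                                                     sw_ppm = 1, si = 4)), 1)
  expect_error(acquisitionParameters(td = 131072, sw_hz = 0),
               "sw_hz")
})

test_that("parameter invariants are enforced by validity", {
  expect_error(new("AcquisitionParameters", td = 1024, sw_hz = 1000,
                   sw_ppm = 2.5, sfo_mhz = 400, ns = 1, ds = 0, d1_s = 1,
                   aq_s = 99, si = 2048, rg = 1, temp_k = 300, lb_hz = 0.3,
                   device = "x"),
               "aq_s inconsistent")
  expect_error(acquisitionParameters(temp_k = -1), "nonpositive")
})

test_that("ppm axis construction covers the width, descending", {
  # two-point case: spacing sw/si
  p2 <- acquisitionParameters(td = 8, sw_hz = 4000, sw_ppm = 10, si = 2)
  ax2 <- buildPpmAxis(p2, center_ppm = 5)
  expect_equal(ax2, c(7.5, 2.5))
  # full-size axis
  p <- devicePreset("UltraShield")
  ax <- buildPpmAxis(p)
  expect_length(ax, 262144)
  expect_true(all(diff(ax) < 0))
  expect_equal(ax[1] - ax[length(ax)], 20.5503 * (262144 - 1) / 262144)
  expect_lte(abs((ax[1] - ax[length(ax)]) - 20.5503),
             20.5503 / 262144 + 1e-12)
  bad <- p; bad@si <- 1
  expect_error(buildPpmAxis(bad), "si")
})

test_that("exponential apodization follows exp(-pi lb t)", {
  p <- deskParams(td = 1024)
  fid <- simulateFid(data.frame(ppm = 5, area = 1, fwhm_hz = 1), p)
  expect_equal(apodizeExponential(fid, 0)@values, fid@values)
  ap <- apodizeExponential(fid, 0.30)
  expect_equal(ap@values[1], fid@values[1])  # t = 0 unchanged
  # attenuation is exactly e^-1 where lb = 1/(pi * t_k)
  k <- 400
  t_k <- (k - 1) * fid@dwell_s
  lb <- 1 / (pi * t_k)
  ap2 <- apodizeExponential(fid, lb)
  expect_equal(Mod(ap2@values[k] / fid@values[k]), exp(-1), tolerance = 1e-12)
  expect_equal(Mod(ap@values[k] / fid@values[k]), exp(-pi * 0.30 * t_k),
               tolerance = 1e-12)
  expect_error(apodizeExponential(fid, -0.1), "lb_hz")
})

test_that("Fourier transform yields a Lorentzian of the expected width", {
  p <- deskParams(td = 16384, si = 32768)
  fid <- simulateFid(data.frame(ppm = 5, area = 3, fwhm_hz = 2), p)
  sp <- phaseCorrect(transformToSpectrum(fid))
  expect_length(intensities(sp), 32768)
  fit <- integrateWindow(sp, c(4.8, 5.2), "linefit")
  expect_equal(fit$fwhm_hz, 2, tolerance = 0.05)
  expect_equal(fit$raw_area, 3, tolerance = 0.01)
  # all-zero FID -> all-zero spectrum
  z <- new("FID", values = complex(real = rep(0, 8192), imaginary = rep(0, 8192)),
           dwell_s = 1 / p@sw_hz, params = p)
  expect_true(all(Mod(intensities(transformToSpectrum(z))) == 0))
  expect_error(transformToSpectrum(fid, zero_fill_to = 100), "zero_fill_to")
})

test_that("automatic phasing recovers injected phase errors", {
  p <- deskParams(td = 8192, si = 16384)
  peaks <- data.frame(ppm = c(3.2, 7.4), area = c(5, 2), fwhm_hz = c(1, 1))
  # already phased: output ~ input
  sp0 <- phaseCorrect(transformToSpectrum(simulateFid(peaks, p)))
  expect_lt(abs(sp0@meta$phase0_deg), 3)
  # 90 degree zero-order rotation recovered as about -90
  sp90 <- phaseCorrect(transformToSpectrum(
    simulateFid(peaks, p, phase0_deg = 90)))
  expect_equal(sp90@meta$phase0_deg, -90, tolerance = 3)
  # first-order gradient injected in the frequency domain: both peaks
  # restored to positive absorption with their areas preserved
  raw <- transformToSpectrum(simulateFid(peaks, p))
  n <- length(raw@intensities)
  frac <- (seq_len(n) - 1) / (n - 1) - 0.5
  twisted <- raw
  twisted@intensities <- raw@intensities * exp(1i * (0.5 + 1.8 * frac))
  fixed <- phaseCorrect(twisted)
  a1 <- integrateWindow(fixed, c(3.0, 3.4), "sum")$raw_area
  a2 <- integrateWindow(fixed, c(7.2, 7.6), "sum")$raw_area
  expect_equal(a1, 5, tolerance = 0.02)
  expect_equal(a2, 2, tolerance = 0.02)
})

test_that("phase correction changes ideal peak integrals by < 0.5%", {
  p <- deskParams(td = 16384, si = 32768)
  fid <- simulateFid(data.frame(ppm = 5, area = 4, fwhm_hz = 2), p)
  sp <- phaseCorrect(transformToSpectrum(apodizeExponential(fid)))
  before <- integrateWindow(sp, c(4, 6), "sum")$raw_area
  expect_equal(before, 4, tolerance = 0.005)
})

test_that("baseline correction removes offsets and ramps", {
  p <- deskParams(si = 8192)
  x <- buildPpmAxis(p)
  peak <- lorentzianPpm(x, 5, 0.003, 10)
  # flat offset restored
  sp <- spectrumFromIntensities(peak + 3, p)
  bc <- baselineCorrect(sp)
  free <- abs(x - 5) > 1
  expect_lt(abs(median(intensities(bc)[free])), 0.05)
  # linear ramp: corrected integral equals the no-ramp integral within 1%
  ref <- integrateWindow(spectrumFromIntensities(peak, p), c(4.8, 5.2), "sum")
  ramp <- baselineCorrect(spectrumFromIntensities(peak + 0.5 * x + 2, p))
  got <- integrateWindow(ramp, c(4.8, 5.2), "sum")
  expect_equal(got$raw_area, ref$raw_area, tolerance = 0.01)
  # zero spectrum stays zero
  z <- baselineCorrect(spectrumFromIntensities(rep(0, 8192), p))
  expect_true(all(abs(intensities(z)) < 1e-10))
  short <- new("NMRSpectrum", intensities = c(3, 2, 1), ppm = c(3, 2, 1),
               params = p, label = "", meta = list())
  expect_error(baselineCorrect(short), "baseline window")
})

test_that("spectrum text round-trip preserves data and metadata", {
  st <- noiselessSettings()
  sim <- simulateSpectrum(c(caffeine = 100), settings = st,
                          params = deskParams(si = 4096))
  path <- tempfile(fileext = ".tsv")
  writeSpectrum(sim$spectrum, path)
  back <- readSpectrum(path)
  expect_equal(ppmAxis(back), ppmAxis(sim$spectrum), tolerance = 1e-12)
  expect_equal(intensities(back), intensities(sim$spectrum), tolerance = 1e-12)
  expect_equal(acqParams(back)@sw_ppm, 20.5503)
  expect_equal(acqParams(back)@td, 16384)
  expect_identical(sampleLabel(back), "simulated")
})

test_that("malformed spectrum files raise parse errors naming the line", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# td=1024", "1.0 2.0", "0.9 3.0 7.0", "0.8 1.0"), path)
  expect_error(readSpectrum(path), "line 3")
  writeLines(c("##TITLE=x", "##NPOINTS=5", "##FIRSTX=10", "##LASTX=0",
               "##XYDATA=(X++(Y..Y))", "10 1 2 3", "##END="), path)
  expect_error(readSpectrum(path), "NPOINTS")
})

test_that("JCAMP-DX text reads to the same spectrum as the tabular dialect", {
  n <- 64
  params <- acquisitionParameters(td = 2 * n, sw_hz = 4000, sw_ppm = 10,
                                  si = n)
  x <- buildPpmAxis(params, center_ppm = 5)
  y <- round(lorentzianPpm(x, 5, 0.05, 10), 6)
  sp <- new("NMRSpectrum", intensities = y, ppm = x, params = params,
            label = "jc", meta = list())
  tab <- tempfile(fileext = ".tsv")
  writeSpectrum(sp, tab)
  jc <- tempfile(fileext = ".jdx")
  rows <- vapply(seq_len(n), function(i) sprintf("%.10f %.6f", x[i], y[i]),
                 character(1))
  writeLines(c("##TITLE=jc", "##XUNITS=PPM", sprintf("##NPOINTS=%d", n),
               sprintf("##FIRSTX=%.10f", x[1]),
               sprintf("##LASTX=%.10f", x[n]),
               "##XYDATA=(X++(Y..Y))", rows, "##END="), jc)
  a <- readSpectrum(tab)
  b <- readSpectrum(jc)
  expect_equal(ppmAxis(b), ppmAxis(a), tolerance = 1e-9)
  expect_equal(intensities(b), intensities(a), tolerance = 1e-9)
})

test_that("total area is invariant under zero-filling level", {
  p <- deskParams(td = 8192, si = 8192)
  fid <- apodizeExponential(
    simulateFid(data.frame(ppm = 5, area = 3, fwhm_hz = 4), p))
  areas <- vapply(c(8192, 16384, 65536), function(zf) {
    sp <- phaseCorrect(transformToSpectrum(fid, zero_fill_to = zf))
    integrateWindow(sp, c(3.5, 6.5), "sum")$raw_area
  }, numeric(1))
  expect_lt(max(abs(areas / areas[1] - 1)), 0.001)
})

test_that("apodization broadens a Lorentzian by LB Hz", {
  p <- deskParams(td = 16384, si = 32768)
  fid <- simulateFid(data.frame(ppm = 5, area = 3, fwhm_hz = 1), p)
  w0 <- integrateWindow(phaseCorrect(transformToSpectrum(fid)),
                        c(4.9, 5.1), "linefit")$fwhm_hz
  w2 <- integrateWindow(phaseCorrect(transformToSpectrum(
    apodizeExponential(fid, 2.0))), c(4.9, 5.1), "linefit")$fwhm_hz
  expect_equal(w2 - w0, 2.0, tolerance = 0.2)
})

test_that("full processing chain reproduces simulator peak areas within 1%", {
  p <- deskParams(td = 16384, si = 32768)
  peaks <- data.frame(ppm = c(3.155, 5.8875, 9.68), area = c(5, 2, 0.5),
                      fwhm_hz = c(1, 1, 1))
  sp <- processSpectrum(simulateFid(peaks, p))
  for (i in seq_len(nrow(peaks))) {
    got <- integrateWindow(sp, peaks$ppm[i] + c(-0.15, 0.15),
                           "linefit")$raw_area
    expect_equal(got, peaks$area[i], tolerance = 0.01)
  }
})
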