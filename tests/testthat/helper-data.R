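# Shared small fixtures, built in code once per test run.

tinyCfg <- generatorConfig(nAnatomies = 3L, nElectrodeConfigs = 2L, seed = 42L)
tinyDb <- generateDatabase(tinyCfg)  # 3 x 12 x 2 = 72 records

# a seeded stream of random beats spanning both chambers
randomBeats <- local({
  sc <- sublocationChamber()
  cfg <- generatorConfig(seed = 4L)
  withr::with_seed(123L, {
    lapply(1:100, function(i) {
      ch <- sample(c("LVOT", "RVOT"), 1L)
      generateBeat(sample(16L, 1L), ch, sample(names(sc)[sc == ch], 1L),
                   sample(13L, 1L), cfg)
    })
  })
})

# a normalized segment with clear positive R / deep S in V4
refSegment <- normalizeAndAlign(randomBeats[[1L]])

# simple 12-row matrix builder for hand-made segments
leadMatrix <- function(L = 160L, fill = 0) {
  matrix(fill, nrow = 12L, ncol = L, dimnames = list(leadNames(), NULL))
}

gaussPulse <- function(L, center, sigma, amp = 1) {
  amp * exp(-((seq_len(L) - center)^2) / (2 * sigma^2))
}
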