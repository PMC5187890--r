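# Independent brute-force oracles and small fixture builders used across the
# suite.  The oracles share no code with the estimators they check.

# exhaustive SSE grid search for F(t) = Finf + A exp(-k t): for each k on the
# grid the best (Finf, A) come from OLS, so the returned k is the global grid
# minimiser of the profiled SSE
gridExpFit <- function(t, f, kGrid) {
  sse <- vapply(kGrid, function(k) {
    x <- exp(-k * t)
    sum(stats::lm.fit(cbind(1, x), f)$residuals^2)
  }, numeric(1))
  kGrid[which.min(sse)]
}

# grid SSE fit of C(t) = C0 exp(-k t) with free amplitude through the origin
gridDecayFit <- function(t, c0t, kGrid) {
  sse <- vapply(kGrid, function(k) {
    x <- exp(-k * t)
    b <- sum(c0t * x) / sum(x * x)
    sum((c0t - b * x)^2)
  }, numeric(1))
  kGrid[which.min(sse)]
}

# wrap raw (times, values) into a ShrinkageTrace with a transparent
# (noiseless, zero-dead-time, unit-gain) instrument
makeShrinkageTrace <- function(times, values, temperature = 296.15) {
  ins <- instrumentSpec(deadTime = 0, duration = max(times) + 1,
                        sampleRate = length(times) / max(times),
                        noiseSd = 0, fluorOffset = 0, fluorGain = 1)
  new("ShrinkageTrace", times = times, fluorescence = values,
      instrument = ins, temperature = temperature,
      condition = list(), groundTruth = list())
}

# linearised shrinkage rate k = Pf (A/V0) Vw osm_out (osm_out in mol/cm^3)
linearShrinkageRate <- function(Pf, diameterUm, osmOut,
                                constants = physicalConstants()) {
  Pf * (6 / (diameterUm * 1e-4)) * constants@Vw * osmOut * 1e-3
}

# per-line membrane-expression values for a cohort of generated cells
syntheticCohortValues <- function(n, expressionTrue, blurSdPx, noiseSd,
                                  seedOffset = 0) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    img <- generateCellImage(expressionTrue, blurSdPx = blurSdPx,
                             noiseSd = noiseSd, seed = i + seedOffset,
                             cellId = paste0("cell", i))
    cl <- img$lines[img$lines$role == "cell", ]
    bg <- img$lines[img$lines$role == "background", ]
    do.call(rbind, lapply(seq_len(nrow(cl)), function(j) {
      pr <- extractProfile(img$image,
                           c(cl$x0[j], cl$y0[j]), c(cl$x1[j], cl$y1[j]),
                           bgStart = c(bg$x0[j], bg$y0[j]),
                           bgEnd = c(bg$x1[j], bg$y1[j]),
                           cellId = cl$cellId[j], lineId = cl$lineId[j])
      data.frame(cellId = cl$cellId[j], lineId = cl$lineId[j],
                 value = as.numeric(relativeMembraneExpression(
                   pr, imageMax = img$groundTruth$imageMax)))
    }))
  }))
}
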