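## Shared fixtures, all built in code.

fixtureScene <- function(seed = 1, nArteries = 1) makeScene(seed, nArteries)

## Hand-placed straight sprouts: one row per requested length, bases spread
## widely along the cut wall so every sprout is resolvable.
manualSprouts <- function(scene, lengthsUm, dpt = 6.5, perfused = NULL,
                          spacingUm = 60) {
  st <- stumps(scene, "distal")[[1]]
  term <- st$terminalUm
  n <- length(lengthsUm)
  if (n == 0L) return(angioQuant:::emptySprouts())
  out <- data.frame(
    sprout_id = sprintf("fix%02d", seq_len(n)),
    side = "distal",
    parent_stump = st$id,
    birth_dpt = 3.5,
    rate_um_per_dpt = lengthsUm / (dpt - 3.5),
    perfused = if (is.null(perfused)) NA else perfused,
    stringsAsFactors = FALSE)
  out$path <- lapply(seq_len(n), function(i) {
    base <- c(term[1] + 10 + (i - 1) * spacingUm, term[2])
    rbind(base, base + c(0, -150))           # straight, wound-ward
  })
  out
}

## Noise-free-ish anatomy render of a scene plus sprouts.
renderFixture <- function(scene, sprouts, dpt = 6.5, res = 256, seed = 1) {
  renderSeries(scene, mode = "anatomy", res = res, sprouts = sprouts,
               dpt = dpt, seed = seed)
}

expect_setequalish <- function(a, b, tol) {
  expect_equal(length(a), length(b))
  expect_true(all(abs(sort(a) - sort(b)) <= tol))
}
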