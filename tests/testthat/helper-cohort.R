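## Shared fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

fixtureCohort <- function() {
  if (is.null(.cache$cohort)) .cache$cohort <- buildFixtureCohort()
  .cache$cohort
}

fixtureProfiles <- function() {
  if (is.null(.cache$profiles))
    .cache$profiles <- summarizeCohort(fixtureCohort())
  .cache$profiles
}

fixtureScores <- function() {
  if (is.null(.cache$scores)) .cache$scores <- hclScore(fixtureProfiles())
  .cache$scores
}

## Minimal event table: tumor fluorescence values for one marker, plus a
## normal-B reference population (constant low values by default).
toyEventTable <- function(tumor, normal = rep(10, 50), marker = "CD25",
                          t4 = numeric(0), t8 = numeric(0)) {
  vals <- c(tumor, normal, t4, t8)
  pop <- factor(rep(c("tumor_B", "normal_B", "T4", "T8"),
                    c(length(tumor), length(normal), length(t4), length(t8))),
                levels = eventPopulations())
  new("EventTable", sampleId = "toy", markers = marker,
      values = matrix(vals, ncol = 1, dimnames = list(NULL, marker)),
      population = pop)
}

## Patient-level call matrix for score tests
callMatrix <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}
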