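## shared fixtures and independent oracles

## memoized small synthetic study reused across test files
.fixture_env <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.fixture_env$study)) {
    spec <- signal_spec(n_proteins = 40, protein_length = c(60, 80),
                        n_antigens = 8, modified_fraction = 0.2,
                        citrulline_planting = 0.5)
    .fixture_env$study <- simulate_study(spec, seed = 7, n_labeled = 40)
  }
  .fixture_env$study
}

small_inference <- function() {
  if (is.null(.fixture_env$inference)) {
    st <- small_study()
    .fixture_env$inference <- peptide_inference(st$experiment, st$design)
  }
  .fixture_env$inference
}

small_features <- function() {
  if (is.null(.fixture_env$features)) {
    st <- small_study()
    .fixture_env$features <- compute_features(st$experiment, st$design,
                                              small_inference())
  }
  .fixture_env$features
}

small_training <- function() {
  if (is.null(.fixture_env$training)) {
    st <- small_study()
    .fixture_env$training <- make_training_labels(st$elisa, small_features(),
                                                  st$experiment, st$design)
  }
  .fixture_env$training
}

## a tiny hand-built library: one protein with 3 tiles, one singleton
tiny_library <- function() {
  recs <- rbind(
    tile_protein("protA", "ACDEFGHIKLMNPQRSTVWY", tile_length = 16, step = 2),
    data.frame(peptide_id = "solo-1", sequence = "ACDEFGHIKLMNPQRS",
               protein_id = "solo", start = 1, modification = "native",
               stringsAsFactors = FALSE)
  )
  peptide_library(recs, step = 2)
}

## exact two-sided rank-sum p by full enumeration of group reassignments
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  r <- rank(pooled)
  center <- n1 * (n + 1) / 2
  dev_obs <- abs(sum(r[seq_len(n1)]) - center)
  idx <- utils::combn(n, n1)
  devs <- abs(colSums(matrix(r[idx], nrow = n1)) - center)
  mean(devs >= dev_obs - 1e-9)
}

## AUC by brute-force pairwise concordance
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

## random tie-free sample pair
random_tiefree_pair <- function(n1, n2) {
  repeat {
    x <- round(stats::rnorm(n1 + n2), 3)
    if (!anyDuplicated(x)) return(list(a = x[seq_len(n1)], b = x[-seq_len(n1)]))
  }
}
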