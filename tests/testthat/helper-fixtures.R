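# Session-cached fixtures: built once, reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

# default small fixture: one species per family + squid-like off-target
fixture_db_small <- function() {
  if (is.null(.fixture_cache$small)) {
    fx <- generate_fixture_refs(1, divergence = 5, seed = 7,
                                dir = file.path(tempdir(), "fx_small"))
    .fixture_cache$small <- build_db(fx$fasta, fx$taxonomy)
    .fixture_cache$small_paths <- fx
  }
  .fixture_cache$small
}

fixture_paths_small <- function() {
  fixture_db_small()
  .fixture_cache$small_paths
}

# full fixture: 3 mussels + 6 scallops + 2 oysters + squid (the published
# reference panel layout)
fixture_db_full <- function() {
  if (is.null(.fixture_cache$full)) {
    fx <- generate_fixture_refs(c(3, 6, 2), divergence = 5, seed = 7,
                                dir = file.path(tempdir(), "fx_full"))
    .fixture_cache$full <- build_db(fx$fasta, fx$taxonomy)
    .fixture_cache$full_paths <- fx
  }
  .fixture_cache$full
}

fixture_paths_full <- function() {
  fixture_db_full()
  .fixture_cache$full_paths
}

# duplicate-mode fixture: two Pecten species share an identical insert
fixture_db_dup <- function() {
  if (is.null(.fixture_cache$dup)) {
    fx <- generate_fixture_refs(c(1, 2, 1), divergence = 5, seed = 7,
                                duplicate_pair = TRUE,
                                dir = file.path(tempdir(), "fx_dup"))
    .fixture_cache$dup <- build_db(fx$fasta, fx$taxonomy)
    .fixture_cache$dup_paths <- fx
  }
  .fixture_cache$dup
}

# 3 sigma band (in percentage points) for a binomial proportion estimate
three_sigma_pct <- function(p, n) 300 * sqrt(p * (1 - p) / n)
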