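test_that("packaged assay holds the seven published primers and adapters", {
  assay <- default_assay()
  tab <- assay_primers(assay)
  expect_equal(nrow(tab), 7)
  expect_equal(sum(tab$direction == "forward"), 3)
  expect_equal(sum(tab$direction == "reverse"), 4)
  expected <- c(
    For_Mu  = "CCTTTTGCATAAGGGTTTTTCAAG",
    Rev1_Mu = "CGAATAGTATCTAGCCGCCATTC",
    Rev2_Mu = "GCAAATAGCATATCACTTTCACCTC",
    For_Sc  = "TGCTAAGGTAGCTAAATTATGGCC",
    Rev_Sc  = "CTTCACGGGGTCTTCTCGTC",
    For_Oy  = "GGTAGCGAAATTCCTTGCCTT",
    Rev_Oy  = "AAAGTTGCACGGGGTCTT")
  expect_equal(setNames(tab$sequence, tab$name), expected)
  expect_equal(assay$overhang_forward, "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG")
  expect_equal(assay$overhang_reverse, "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG")
  # mussel forward primer runs at doubled concentration
  expect_equal(tab$concentration_uM[tab$name == "For_Mu"], 0.4)
  expect_true(all(tab$concentration_uM[tab$name != "For_Mu"] == 0.2))
})

test_that("assay YAML config round-trips the packaged assay", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_assay(default_assay(), path)
  again <- read_assay(path)
  expect_equal(assay_primers(again), assay_primers(default_assay()))
  expect_equal(again$overhang_forward, default_assay()$overhang_forward)
  # the installed copy matches too
  pkg_yaml <- system.file("extdata", "triplex_assay.yaml",
                          package = "bivalvID")
  expect_equal(assay_primers(read_assay(pkg_yaml)),
               assay_primers(default_assay()))
})

test_that("mismatch_count follows the IUPAC expansion rule", {
  expect_equal(mismatch_count("AAAGTTGCACGGGGTCTT", "AAAGTTGCACGGGGTCTT"), 0)
  expect_equal(mismatch_count("NNNN", "ACGT"), 0)
  s <- "CCTTTTGCATAAGGGTTTTTCAAG"
  mutated <- paste0(substr(s, 1, 9), "A", substr(s, 11, nchar(s)))  # T10->A
  expect_equal(mismatch_count(s, mutated), 1)
  expect_error(mismatch_count("ACGT", "ACG"), "equal length")
  # ambiguity codes in the window never match
  expect_equal(mismatch_count("N", "N"), 1)
})

test_that("mismatch_count is zero iff the window is in the primer expansion", {
  set.seed(11)
  for (rep in 1:20) {
    primer <- paste(sample(c("A", "C", "G", "T", "R", "Y", "N", "W"), 6,
                           replace = TRUE), collapse = "")
    expansions <- oracle_expand(primer)
    windows <- unique(c(sample(expansions, min(5, length(expansions))),
                        replicate(5, paste(sample(c("A", "C", "G", "T"), 6,
                                                  replace = TRUE),
                                           collapse = ""))))
    for (w in windows) {
      expect_equal(mismatch_count(primer, w) == 0, w %in% expansions,
                   info = paste(primer, w))
      expect_equal(mismatch_count(primer, w), oracle_mismatch(primer, w),
                   info = paste(primer, w))
    }
  }
})

test_that("Wallace-rule Tm matches hand counts and rejects ambiguity", {
  expect_equal(tm_wallace("AAAA"), 8)
  expect_equal(tm_wallace("GGGG"), 16)
  # AAAGTTGCACGGGGTCTT: 4 A + 5 T, 6 G + 3 C -> 2*9 + 4*9 = 54
  expect_equal(tm_wallace("AAAGTTGCACGGGGTCTT"), 54)
  expect_error(tm_wallace("ACGN"), "unambiguous")
})

test_that("self-complementarity score matches the brute-force oracle", {
  expect_equal(self_complement_score("ACGT"), 4)
  expect_equal(self_complement_score("AAAA"), 0)
  for (p in assay_primers(default_assay())$sequence)
    expect_equal(self_complement_score(p), oracle_self_complement(p), info = p)
})

test_that("with_overhang prefixes the correct adapter", {
  assay <- default_assay()
  for_mu <- assay$sets$Mytilidae$forwards[[1]]
  expect_equal(with_overhang(for_mu, assay),
               paste0("TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
                      "CCTTTTGCATAAGGGTTTTTCAAG"))
  rev_oy <- assay$sets$Ostreidae$reverses[[1]]
  expect_equal(with_overhang(rev_oy, assay),
               paste0("GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG",
                      "AAAGTTGCACGGGGTCTT"))
  alien <- primer("alien", "ACGTACGTACGTACGTACGT", "forward", "Mytilidae")
  expect_error(with_overhang(alien, assay), "not part of the assay")
  expect_error(primer("empty", "", "forward", "Mytilidae"))
})

test_that("binding-site search finds planted sites with the 3'-anchor rule", {
  assay <- default_assay()
  for_sc <- assay$sets$Pectinidae$forwards[[1]]
  set.seed(21)
  left <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                 collapse = "")
  tmpl <- paste0(left, for_sc$sequence, right)

  sites <- find_binding_sites(tmpl, for_sc, max_mm = 0)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$strand, "+")
  expect_equal(sites$start, 40)
  expect_equal(sites$end, 40 + nchar(for_sc$sequence))
  expect_equal(sites$mismatches, 0)

  # strand symmetry: the reverse complement template reports the site on "-"
  sites_rc <- find_binding_sites(oracle_revcomp(tmpl), for_sc, max_mm = 0)
  expect_equal(nrow(sites_rc), 1)
  expect_equal(sites_rc$strand, "-")
  expect_equal(sites_rc$start, 40)  # mirrored coordinates

  # one internal mismatch is reported; the same mismatch at the 3'-terminal
  # base is not
  seq <- for_sc$sequence
  internal <- seq
  substr(internal, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                    substr(seq, 5, 5))[1]
  tmpl_int <- paste0(left, internal, right)
  s <- find_binding_sites(tmpl_int, for_sc, max_mm = 2)
  expect_equal(s$mismatches[s$strand == "+"], 1)
  terminal <- seq
  substr(terminal, nchar(seq), nchar(seq)) <-
    setdiff(c("A", "C", "G", "T"), substr(seq, nchar(seq), nchar(seq)))[1]
  tmpl_term <- paste0(left, terminal, right)
  s <- find_binding_sites(tmpl_term, for_sc, max_mm = 2)
  expect_false(any(s$strand == "+" & s$start == 40))
})

test_that("binding-site search agrees with the exhaustive scan oracle", {
  assay <- default_assay()
  set.seed(33)
  primers <- unlist(lapply(assay$sets, function(s) c(s$forwards, s$reverses)),
                    recursive = FALSE)
  for (rep in 1:5) {
    tmpl <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                  collapse = "")
    p <- primers[[sample(length(primers), 1)]]
    # plant a site with one internal mismatch
    site <- p$sequence
    substr(site, 7, 7) <- setdiff(c("A", "C", "G", "T"),
                                  substr(site, 7, 7))[1]
    tmpl <- paste0(substr(tmpl, 1, 100), site, substr(tmpl, 101, 300))
    got <- find_binding_sites(tmpl, p, max_mm = 2)
    plus <- oracle_scan(tmpl, p$sequence, 2, "end")
    minus <- oracle_scan(tmpl, oracle_revcomp(p$sequence), 2, "start")
    expect_setequal(got$start[got$strand == "+"], plus$start)
    expect_setequal(got$start[got$strand == "-"], minus$start)
  }
})

test_that("reverse complement is an involution and matches the oracle", {
  set.seed(5)
  for (rep in 1:25) {
    s <- paste(sample(names(ORACLE_IUPAC), sample(1:60, 1), replace = TRUE),
               collapse = "")
    expect_equal(revcomp(revcomp(s)), s)
    expect_equal(revcomp(s), oracle_revcomp(s))
  }
})
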