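test_that("loading the reference panel preserves records and canonicalizes synonyms", {
  fx <- fixture_paths_full()
  db <- load_references(fx$fasta, fx$taxonomy)
  expect_s3_class(db, "barcode_db")
  expect_equal(nrow(db$records), 12)  # 11 bivalves + squid-like off-target
  # the oyster written under its former name loads as the canonical species
  expect_false("Crassostrea gigas" %in% db$records$species)
  expect_true("Magallana gigas" %in% db$records$species)
  expect_equal(db$records$genus[db$records$species == "Magallana gigas"],
               "Magallana")
  expect_true(all(db$records$sequence == toupper(db$records$sequence)))
})

test_that("records with non-IUPAC characters are rejected and reported", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "refs.fasta")
  writeLines(c(">GOOD1", strrep("ACGT", 50),
               ">BAD1", paste0(strrep("ACGT", 49), "ACGX")), fa)
  tx <- file.path(dir, "tax.tsv")
  writeLines(c("accession\tspecies\tgenus\tfamily",
               "GOOD1\tMytilus edulis\tMytilus\tMytilidae",
               "BAD1\tOstrea edulis\tOstrea\tOstreidae"), tx)
  db <- load_references(fa, tx)
  expect_equal(db$records$accession, "GOOD1")
  rep_ <- db$load_report
  expect_equal(rep_$status[rep_$accession == "BAD1"], "rejected")
  expect_match(rep_$reason[rep_$accession == "BAD1"], "non-IUPAC")
})

test_that("loader errors name the offending accession", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "refs.fasta")
  writeLines(c(">ACC1", strrep("ACGT", 30)), fa)
  tx <- file.path(dir, "tax.tsv")
  writeLines(c("accession\tspecies\tgenus\tfamily",
               "OTHER\tMytilus edulis\tMytilus\tMytilidae"), tx)
  expect_error(load_references(fa, tx), "ACC1")

  writeLines(c(">ACC1", strrep("ACGT", 30), ">ACC1", strrep("ACGT", 30)), fa)
  writeLines(c("accession\tspecies\tgenus\tfamily",
               "ACC1\tMytilus edulis\tMytilus\tMytilidae"), tx)
  expect_error(load_references(fa, tx), "duplicate")
})

test_that("inserts are primer-free with the expected per-family lengths", {
  db <- fixture_db_full()
  assay <- default_assay()
  expected_len <- c(
    Mytilidae = 150 - nchar("CCTTTTGCATAAGGGTTTTTCAAG") -
      nchar("CGAATAGTATCTAGCCGCCATTC"),
    Pectinidae = 150 - nchar("TGCTAAGGTAGCTAAATTATGGCC") -
      nchar("CTTCACGGGGTCTTCTCGTC"),
    Ostreidae = 150 - nchar("GGTAGCGAAATTCCTTGCCTT") -
      nchar("AAAGTTGCACGGGGTCTT"))
  for (acc in names(db$inserts)) {
    fam <- db$records$family[db$records$accession == acc]
    expect_equal(nchar(db$inserts[[acc]]), unname(expected_len[fam]),
                 info = acc)
    # insert carries no primer sequence at its ends
    amp <- db$amplicons[[acc]]
    expect_equal(amp$insert[1], db$inserts[[acc]])
    expect_equal(nchar(amp$sequence[1]), 150)
  }
  # the squid-like record is non-amplifiable
  squid <- db$records$accession[db$records$species == "Sepiella inermis"]
  expect_false(squid %in% names(db$inserts))
  expect_false(db$flags$amplifiable[db$flags$accession == squid])
})

test_that("a record amplifiable by two primer placements is flagged ambiguous", {
  assay <- default_assay()
  set.seed(61)
  fwd <- assay$sets$Mytilidae$forwards[[1]]$sequence
  rev1 <- assay$sets$Mytilidae$reverses[[1]]$sequence
  rev2 <- assay$sets$Mytilidae$reverses[[2]]$sequence
  mid1 <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  mid2 <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                collapse = "")
  tmpl <- paste0("ACGTACGTAC", fwd, mid1, oracle_revcomp(rev1), mid2,
                 oracle_revcomp(rev2), "ACGTACGTAC")
  dir <- withr::local_tempdir()
  writeLines(c(">AMB1", tmpl), file.path(dir, "refs.fasta"))
  writeLines(c("accession\tspecies\tgenus\tfamily",
               "AMB1\tMytilus edulis\tMytilus\tMytilidae"),
             file.path(dir, "tax.tsv"))
  db <- load_references(file.path(dir, "refs.fasta"),
                        file.path(dir, "tax.tsv"))
  expect_message(db <- build_inserts(db, assay), "ambiguous")
  expect_true(db$flags$ambiguous[db$flags$accession == "AMB1"])
  # the shortest product is kept
  amp <- db$amplicons[["AMB1"]]
  expect_equal(nrow(amp), 2)
  expect_equal(db$inserts[["AMB1"]], amp$insert[1])
  expect_lt(amp$length[1], amp$length[2])
})

test_that("resolution groups partition species and label by insert identity", {
  db <- fixture_db_full()
  g <- db$groups
  # all-distinct fixture: every amplifiable species is a singleton
  amp_groups <- g[g$label != "non-amplifiable", ]
  expect_true(all(amp_groups$n == 1))
  expect_equal(sort(unlist(amp_groups$members)), sort(amp_groups$label))
  # partition: disjoint and covering
  all_members <- unlist(g$members)
  expect_equal(sort(all_members), sort(unique(db$records$species)))
  expect_false(anyDuplicated(all_members) > 0)
})

test_that("duplicate inserts within a genus collapse to a 'Genus spp.' group", {
  db <- fixture_db_dup()
  g <- db$groups
  pecten <- g[g$label == "Pecten spp.", ]
  expect_equal(nrow(pecten), 1)
  expect_setequal(pecten$members[[1]], c("Pecten jacobaeus", "Pecten maximus"))
  # label soundness across all groups
  for (i in seq_len(nrow(g))) {
    lbl <- g$label[i]
    members <- g$members[[i]]
    if (grepl(" spp\\.$", lbl)) {
      expect_gt(length(members), 1)
      genera <- unique(vapply(strsplit(members, " "), `[[`, "", 1))
      expect_equal(paste(genera, "spp."), lbl)
    }
  }
})

test_that("identical inserts across genera get a slash label, never 'spp.'", {
  assay <- default_assay()
  set.seed(71)
  fwd <- assay$sets$Ostreidae$forwards[[1]]$sequence
  rev <- assay$sets$Ostreidae$reverses[[1]]$sequence
  ins <- paste(sample(c("A", "C", "G", "T"), 111, replace = TRUE),
               collapse = "")
  tmpl <- paste0("GATTACAGATTACA", fwd, ins, oracle_revcomp(rev), "TTGGCCAA")
  dir <- withr::local_tempdir()
  writeLines(c(">X1", tmpl, ">X2", tmpl), file.path(dir, "refs.fasta"))
  writeLines(c("accession\tspecies\tgenus\tfamily",
               "X1\tMagallana gigas\tMagallana\tOstreidae",
               "X2\tOstrea edulis\tOstrea\tOstreidae"),
             file.path(dir, "tax.tsv"))
  db <- build_db(file.path(dir, "refs.fasta"), file.path(dir, "tax.tsv"))
  g <- db$groups
  expect_true("Magallana gigas/Ostrea edulis" %in% g$label)
  expect_false(any(grepl("spp\\.", g$label)))
})

test_that("a database bundle round-trips through write_db/read_db", {
  db <- fixture_db_full()
  dir <- withr::local_tempdir()
  write_db(db, dir)
  expect_true(all(file.exists(file.path(dir,
    c("references.fasta", "taxonomy.tsv", "inserts.fasta", "groups.tsv",
      "load_report.txt")))))
  db2 <- read_db(dir)
  expect_equal(db2$records[order(db2$records$accession), ],
               db$records[order(db$records$accession), ],
               ignore_attr = TRUE)
  expect_equal(db2$inserts, db$inserts)
  expect_equal(db2$groups$label, db$groups$label)
  expect_equal(db2$groups$members, db$groups$members)
})
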