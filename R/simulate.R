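# Seeded simulation: synthetic bivalve-like reference fixtures carrying the
# packaged primer binding sites, and paired-end FASTQ reads drawn from DNA
# extract mixture specifications.

# Species pools used by the fixture generator, ordered so small fixtures pick
# the species used in the published mixture designs first.
FIXTURE_SPECIES <- list(
  Mytilidae = c("Mytilus galloprovincialis", "Perna canaliculus",
                "Mytilus edulis"),
  Pectinidae = c("Pecten jacobaeus", "Placopecten magellanicus",
                 "Mizuhopecten yessoensis", "Zygochlamys patagonica",
                 "Argopecten purpuratus", "Aequipecten opercularis"),
  Ostreidae = c("Magallana gigas", "Ostrea edulis")
)

#' Generate a synthetic reference fixture
#'
#' Writes a bivalve-like reference FASTA plus matching taxonomy TSV. Each
#' on-target record embeds its family's exact published primer binding sites
#' flanking a randomized insert such that the primer-inclusive product is
#' exactly 150 bp (Mytilidae records use the first reverse primer). Inserts
#' within a family differ pairwise by at least `divergence` substitutions.
#' One off-target "squid-like" record (*Sepiella inermis*) without any primer
#' binding site is appended. Deterministic under `seed`. All sequences are
#' synthetic; only the primer binding sites are real.
#'
#' @param n_per_family Species per family; length 1 (recycled) or 3 in the
#'   order Mytilidae, Pectinidae, Ostreidae. Zeros allowed.
#' @param divergence Minimum pairwise substitutions between same-family
#'   inserts (>= 1).
#' @param seed Integer RNG seed.
#' @param dir Output directory.
#' @param assay Assay whose binding sites are embedded.
#' @param include_offtarget Append the squid-like record?
#' @param duplicate_pair If `TRUE` and at least two Pectinidae species are
#'   requested, the first two are replaced by two *Pecten* species sharing an
#'   identical insert (exercises genus-level resolution groups).
#' @param flank Random flanking bases on each side of the product.
#' @return List with elements `fasta` and `taxonomy` (file paths).
#' @export
generate_fixture_refs <- function(n_per_family = 1, divergence = 5, seed = 1,
                                  dir = tempdir(), assay = default_assay(),
                                  include_offtarget = TRUE,
                                  duplicate_pair = FALSE, flank = 30) {
  stopifnot(divergence >= 1)
  n <- as.integer(n_per_family)
  if (length(n) == 1) n <- rep(n, 3)
  stopifnot(length(n) == 3, all(n >= 0), any(n > 0) || include_offtarget)
  families <- names(FIXTURE_SPECIES)
  names(n) <- families

  withr::with_seed(seed, {
    recs <- list()
    for (fam in families) {
      if (n[[fam]] == 0) next
      set <- assay$sets[[fam]]
      fwd <- set$forwards[[1]]$sequence
      rev <- set$reverses[[1]]$sequence
      insert_len <- 150 - nchar(fwd) - nchar(rev)
      if (n[[fam]] * divergence > insert_len)
        stop("cannot place ", n[[fam]], " species with pairwise divergence ",
             divergence, " in a ", insert_len, " bp insert (", fam, ")")
      pool <- FIXTURE_SPECIES[[fam]]
      sp <- if (n[[fam]] <= length(pool)) pool[seq_len(n[[fam]])]
      else c(pool, paste(vapply(strsplit(pool[1], " "), `[[`, "", 1),
                         sprintf("simulatus%02d", seq_len(n[[fam]] - length(pool)))))
      if (duplicate_pair && fam == "Pectinidae" && n[[fam]] >= 2)
        sp[1:2] <- c("Pecten jacobaeus", "Pecten maximus")
      base <- random_dna(1, insert_len)
      for (i in seq_along(sp)) {
        ok <- FALSE
        for (try in 1:20) {
          ins <- mutate_block(base, (i - 1) * divergence + seq_len(divergence))
          if (duplicate_pair && fam == "Pectinidae" && i == 2)
            ins <- recs[[length(recs)]]$insert  # identical to Pecten jacobaeus
          template <- paste0(random_dna(1, flank), fwd, ins, revcomp(rev),
                             random_dna(1, flank))
          amp <- predict_amplicons(template, assay, max_mm = 2)
          if (nrow(amp) == 1 && amp$length == 150 && amp$insert == ins) {
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not construct a clean template for ", sp[i])
        recs[[length(recs) + 1]] <- list(
          species = sp[i], family = fam, sequence = template, insert = ins)
      }
    }
    if (include_offtarget) {
      for (try in 1:20) {
        template <- random_dna(1, 260)
        amp <- predict_amplicons(template, assay, max_mm = 2)
        sites <- sum(vapply(unlist(lapply(assay$sets, function(s)
          c(s$forwards, s$reverses)), recursive = FALSE), function(p)
            nrow(find_binding_sites(template, p, max_mm = 2)), integer(1)))
        if (nrow(amp) == 0 && sites == 0) break
      }
      recs[[length(recs) + 1]] <- list(species = "Sepiella inermis",
                                       family = "Sepiidae",
                                       sequence = template, insert = NA)
    }
  })

  acc <- sprintf("SYN%04d", seq_along(recs))
  species <- vapply(recs, `[[`, "", "species")
  # exercise the synonym path: the first Magallana gigas record is written
  # under its former name
  written <- species
  m <- match("Magallana gigas", species)
  if (!is.na(m)) written[m] <- "Crassostrea gigas"
  tax <- data.frame(
    accession = acc, species = written,
    genus = vapply(strsplit(written, " "), `[[`, "", 1),
    family = vapply(recs, `[[`, "", "family"),
    synonyms = "", is_complete_reference = TRUE,
    stringsAsFactors = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "fixture_refs.fasta")
  taxonomy <- file.path(dir, "fixture_taxonomy.tsv")
  write_fasta(setNames(vapply(recs, `[[`, "", "sequence"), acc), fasta)
  write.table(tax, taxonomy, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, taxonomy = taxonomy)
}

# substitute the given positions of a sequence with a different random base
#' @keywords internal
mutate_block <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  stopifnot(max(positions) <= length(ch))
  for (p in positions)
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

#' Simulation error model
#'
#' Substitution-only error model with constant base quality; indels,
#' quality-profile realism and chimeras are out of scope.
#'
#' @param substitution_rate Per-base substitution probability in `[0, 0.5)`.
#' @param read_length Read length in bp (300-cycle kit: 2 x 151).
#' @param quality_char Constant Phred+33 quality symbol for simulated bases.
#' @return An `error_model` object.
#' @export
error_model <- function(substitution_rate = 0.001, read_length = 151L,
                        quality_char = "I") {
  stopifnot(substitution_rate >= 0, substitution_rate < 0.5,
            read_length >= 50, nchar(quality_char) == 1)
  structure(list(substitution_rate = substitution_rate,
                 read_length = as.integer(read_length),
                 quality_char = quality_char),
            class = "error_model")
}

#' Mixture specification
#'
#' Species and DNA proportions of one extract mixture, the ground truth for
#' the simulator.
#'
#' @param species Character vector of species names (canonical or synonym).
#' @param proportions Numeric proportions summing to 1 (tolerance 1e-9).
#' @param total_read_pairs Total read pairs to allocate across components.
#' @param label Sample label.
#' @return A `mixture_spec` object.
#' @export
mixture_spec <- function(species, proportions, total_read_pairs = 50000L,
                         label = "mixture") {
  stopifnot(length(species) == length(proportions), length(species) >= 1,
            total_read_pairs >= 1)
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1 (got ", sum(proportions), ")")
  structure(list(species = species, proportions = proportions,
                 total_read_pairs = as.integer(total_read_pairs),
                 label = label),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("<mixture_spec> %s: %d pairs\n", x$label, x$total_read_pairs))
  for (i in seq_along(x$species))
    cat(sprintf("  %-30s %6.2f%%\n", x$species[i], 100 * x$proportions[i]))
  invisible(x)
}

#' Simulate paired-end reads from a mixture
#'
#' Read-pair counts per component are drawn multinomially with the specified
#' proportions. Off-target components (species without an amplicon in `db`)
#' receive their multinomial allocation but emit no read pairs — their
#' template is never amplified. R1 covers the amplicon 5' end, R2 is the
#' reverse complement of the 3' end; substitution errors are i.i.d. per base.
#' Deterministic under `seed`.
#'
#' @param db A built `barcode_db`.
#' @param mix A [mixture_spec()].
#' @param err An [error_model()].
#' @param seed Integer RNG seed (mandatory).
#' @param dir Output directory.
#' @param efficiency Optional named per-species amplification-efficiency
#'   multipliers (default 1 for every species).
#' @return List: `r1`, `r2` (FASTQ paths), `truth` (TSV path), and
#'   `counts` — a data.frame of per-component allocated/emitted pairs.
#' @export
simulate_sample <- function(db, mix, err = error_model(), seed,
                            dir = tempdir(), efficiency = NULL) {
  stopifnot(inherits(db, "barcode_db"), inherits(mix, "mixture_spec"),
            inherits(err, "error_model"), !missing(seed))
  species <- canonical_species(mix$species, db$synonyms)
  amp_for <- function(sp) {
    accs <- db$records$accession[db$records$species == sp]
    accs <- accs[accs %in% db$flags$accession[db$flags$preferred]]
    if (!length(accs)) return(NULL)
    a <- db$amplicons[[accs[1]]]
    if (is.null(a) || nrow(a) == 0) NULL else a[1, ]  # shortest product
  }
  amps <- lapply(species, amp_for)
  on_target <- !vapply(amps, is.null, logical(1))
  if (!any(on_target))
    warning("all mixture components are off-target; FASTQ will be empty")

  props <- mix$proportions
  if (!is.null(efficiency)) {
    effs <- ifelse(species %in% names(efficiency),
                   efficiency[species], 1)
    props <- props * effs
    props <- props / sum(props)
  }

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  safe <- gsub("[^A-Za-z0-9_.-]", "_", mix$label)
  r1_path <- file.path(dir, paste0(safe, "_R1.fastq"))
  r2_path <- file.path(dir, paste0(safe, "_R2.fastq"))
  truth_path <- file.path(dir, paste0(safe, "_truth.tsv"))

  withr::with_seed(seed, {
    alloc <- as.integer(rmultinom(1, mix$total_read_pairs, props))
    r1 <- character(0); r2 <- character(0); ids <- character(0)
    truth <- character(0)
    idx0 <- 0L
    for (i in seq_along(species)) {
      if (!on_target[i] || alloc[i] == 0) next
      a <- amps[[i]]
      L <- min(err$read_length, nchar(a$sequence))
      r1_base <- substr(a$sequence, 1, L)
      r2_base <- revcomp(substr(a$sequence, nchar(a$sequence) - L + 1,
                                nchar(a$sequence)))
      ids_i <- sprintf("r%07d|%s", idx0 + seq_len(alloc[i]),
                       gsub(" ", "_", species[i]))
      r1 <- c(r1, mutate_reads(rep(r1_base, alloc[i]), err$substitution_rate))
      r2 <- c(r2, mutate_reads(rep(r2_base, alloc[i]), err$substitution_rate))
      ids <- c(ids, ids_i)
      truth <- c(truth, sprintf("%s\t%s", ids_i, species[i]))
      idx0 <- idx0 + alloc[i]
    }
  })
  write_fastq(r1, ids, r1_path, quality_char = err$quality_char)
  write_fastq(r2, ids, r2_path, quality_char = err$quality_char)
  writeLines(c("read_id\tspecies", truth), truth_path)
  list(r1 = r1_path, r2 = r2_path, truth = truth_path,
       counts = data.frame(species = species, proportion = mix$proportions,
                           on_target = on_target, allocated = alloc,
                           emitted = ifelse(on_target, alloc, 0L),
                           stringsAsFactors = FALSE))
}

# i.i.d. per-base substitutions at the given rate
#' @keywords internal
mutate_reads <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  L <- nchar(seqs[1])
  k <- rbinom(length(seqs), L, rate)
  for (i in which(k > 0)) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(L, k[i])
    for (p in pos)
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}
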