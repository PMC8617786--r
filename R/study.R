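# Experiment drivers reproducing the published mixture designs, and the
# mixture-study table with per-replicate results and across-replicate means.

#' The ternary DNA extract mixture design
#'
#' One species per bivalve family mixed 98.0 : 1.5 : 0.5 — scallop
#' (*Pecten jacobaeus*, standing for *Pecten* spp. DNA), oyster
#' (*Magallana gigas*) and mussel (*Mytilus galloprovincialis*).
#'
#' @param total_read_pairs Read pairs to simulate.
#' @return A [mixture_spec()].
#' @export
ternary_mixture_spec <- function(total_read_pairs = 50000L) {
  mixture_spec(
    species = c("Pecten jacobaeus", "Magallana gigas",
                "Mytilus galloprovincialis"),
    proportions = c(0.98, 0.015, 0.005),
    total_read_pairs = total_read_pairs,
    label = "ternary_98.0_1.5_0.5")
}

#' All six ternary mixture permutations
#'
#' The published ternary study assigns the 98.0/1.5/0.5 proportions to every
#' ordering of the three species.
#'
#' @param total_read_pairs Read pairs per mixture.
#' @return List of six [mixture_spec()] objects.
#' @export
ternary_design <- function(total_read_pairs = 50000L) {
  sp <- c("Magallana gigas", "Mytilus galloprovincialis", "Pecten jacobaeus")
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(3, 1, 2), c(3, 2, 1),
                c(2, 3, 1), c(2, 1, 3))
  lapply(seq_along(perms), function(i) {
    ord <- sp[perms[[i]]]
    mixture_spec(ord, c(0.98, 0.015, 0.005),
                 total_read_pairs = total_read_pairs,
                 label = paste0("ternary_", i, "_",
                                gsub(" ", ".", ord[1])))
  })
}

#' Single-family mixture designs
#'
#' The published within-family designs: a scallop mixture (main
#' *Placopecten magellanicus*, five scallop minors at 1.0% each), a mixture
#' with the two oyster species as 1.0% minors, a mussel mixture (main
#' *Perna canaliculus*, two mussel minors at 1.0%), and a squid mixture with
#' off-target *Sepiella inermis* as 97.0% main component plus three bivalves
#' at 1.0% each.
#'
#' @param total_read_pairs Read pairs per mixture.
#' @return Named list of [mixture_spec()] objects.
#' @export
single_family_design <- function(total_read_pairs = 50000L) {
  list(
    scallops = mixture_spec(
      c("Placopecten magellanicus", "Mizuhopecten yessoensis",
        "Pecten jacobaeus", "Zygochlamys patagonica",
        "Argopecten purpuratus", "Aequipecten opercularis"),
      c(0.95, rep(0.01, 5)), total_read_pairs, "single_family_scallops"),
    oysters = mixture_spec(
      c("Placopecten magellanicus", "Magallana gigas", "Ostrea edulis"),
      c(0.98, 0.01, 0.01), total_read_pairs, "single_family_oysters"),
    mussels = mixture_spec(
      c("Perna canaliculus", "Mytilus galloprovincialis", "Mytilus edulis"),
      c(0.98, 0.01, 0.01), total_read_pairs, "single_family_mussels"),
    squid = mixture_spec(
      c("Sepiella inermis", "Placopecten magellanicus", "Ostrea edulis",
        "Perna canaliculus"),
      c(0.97, 0.01, 0.01, 0.01), total_read_pairs, "squid_main"))
}

#' Simulate and analyze a set of mixtures with replicates
#'
#' For each mixture and replicate: simulate reads, run the full workflow, and
#' collect the per-component results. Deterministic: replicate `r` of mixture
#' `m` uses seed `seed + 1000 * m + r`.
#'
#' @param db A built `barcode_db`.
#' @param mixtures List of [mixture_spec()] objects.
#' @param replicates Replicates per mixture (0 yields an empty table with a
#'   warning).
#' @param seed Base integer seed.
#' @param assay A [triplex_assay()].
#' @param err An [error_model()].
#' @param params See [pipeline_params()].
#' @param dir Scratch directory for simulated FASTQ files.
#' @return List with `results` (per mixture x replicate x component:
#'   specified proportion, reads assigned, percent) and `summary`
#'   (across-replicate arithmetic means of the percentages).
#' @export
mixture_study <- function(db, mixtures, replicates = 3, seed = 1,
                          assay = default_assay(), err = error_model(),
                          params = pipeline_params(), dir = tempdir()) {
  stopifnot(inherits(db, "barcode_db"), is.list(mixtures))
  known <- c(unique(db$records$species), names(db$synonyms))
  for (mx in mixtures) {
    stopifnot(inherits(mx, "mixture_spec"))
    unknown <- setdiff(mx$species, known)
    if (length(unknown))
      stop("mixture '", mx$label, "' names species absent from the database: ",
           paste(unknown, collapse = ", "))
  }
  empty <- data.frame(mixture = character(0), replicate = integer(0),
                      species = character(0), label = character(0),
                      true_percent = numeric(0), raw_reads = integer(0),
                      reads_passing = integer(0), reads_assigned = integer(0),
                      percent_assigned = numeric(0), detected = logical(0),
                      stringsAsFactors = FALSE)
  if (replicates < 1) {
    warning("replicates = 0: returning empty study table")
    return(list(results = empty, summary = empty[0, c(1, 3, 5)]))
  }
  rows <- list()
  for (m in seq_along(mixtures)) {
    mx <- mixtures[[m]]
    lab <- species_labels(db)
    for (r in seq_len(replicates)) {
      run_seed <- seed + 1000L * m + r
      sim <- simulate_sample(db, mx, err = err, seed = run_seed, dir = dir)
      rep_ <- run_sample(sim$r1, sim$r2, db, assay = assay, params = params,
                         sample_id = sprintf("%s_rep%d", mx$label, r))
      species <- canonical_species(mx$species, db$synonyms)
      comp_lab <- ifelse(species %in% names(lab), lab[species], species)
      got <- match(comp_lab, rep_$table$label)
      rows[[length(rows) + 1]] <- data.frame(
        mixture = mx$label, replicate = r, species = species,
        label = comp_lab, true_percent = 100 * mx$proportions,
        raw_reads = rep_$total_raw_reads,
        reads_passing = rep_$reads_passing_workflow,
        reads_assigned = ifelse(is.na(got), 0L,
                                rep_$table$reads_assigned[got]),
        percent_assigned = ifelse(is.na(got), 0,
                                  rep_$table$percent_assigned[got]),
        detected = !is.na(got) & rep_$table$detected[got],
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  agg <- aggregate(percent_assigned ~ mixture + species + true_percent,
                   data = results, FUN = mean)
  agg <- agg[order(agg$mixture, -agg$true_percent), , drop = FALSE]
  names(agg)[names(agg) == "percent_assigned"] <- "mean_percent_assigned"
  rownames(agg) <- NULL
  list(results = results, summary = agg)
}
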