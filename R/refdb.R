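# Customized barcode reference database: records loaded from FASTA + taxonomy
# TSV, amplicon inserts derived by in-silico PCR, and species-resolution
# groups derived from exact insert identity.

#' Packaged synonym table
#'
#' Maps former scientific names to the canonical name used in reports.
#' Extensible: taxonomy TSVs may list extra synonyms per record.
#'
#' @return Named character vector, `synonym -> canonical species`.
#' @export
default_synonyms <- function() {
  c("Crassostrea gigas"       = "Magallana gigas",
    "Crassostrea bilineata"   = "Magallana bilineata",
    "Patinopecten yessoensis" = "Mizuhopecten yessoensis")
}

#' @keywords internal
canonical_species <- function(species, synonyms = default_synonyms()) {
  hit <- species %in% names(synonyms)
  species[hit] <- unname(synonyms[species[hit]])
  species
}

#' Load reference sequences and taxonomy into a barcode database
#'
#' Reads a FASTA of reference sequences and a tab-separated taxonomy table
#' with columns `accession`, `species`, `genus`, `family` and optionally
#' `synonyms` (comma-separated) and `is_complete_reference`. Sequences are
#' uppercased; species names are canonicalized through the synonym table;
#' records containing characters outside the IUPAC alphabet are rejected and
#' listed in the load report.
#'
#' @param fasta_path Path to the reference FASTA (IDs = accessions).
#' @param taxonomy_path Path to the taxonomy TSV.
#' @param synonyms Synonym map as in [default_synonyms()]; per-record
#'   synonyms from the TSV are added to it.
#' @return A `barcode_db` object with `records` and `load_report`; inserts
#'   and groups are populated by [build_inserts()] and [resolution_groups()].
#' @export
load_references <- function(fasta_path, taxonomy_path,
                            synonyms = default_synonyms()) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  if (!file.exists(taxonomy_path)) stop("taxonomy not found: ", taxonomy_path)
  seqs <- read_fasta(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))  # accession = first token
  tax <- read.delim(taxonomy_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("accession", "species", "genus", "family")
  if (!all(need %in% names(tax)))
    stop("taxonomy must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(names(seqs)))
    stop("duplicate accession in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (anyDuplicated(tax$accession))
    stop("duplicate accession in taxonomy: ",
         paste(unique(tax$accession[duplicated(tax$accession)]), collapse = ", "))
  missing <- setdiff(names(seqs), tax$accession)
  if (length(missing))
    stop("no taxonomy row for FASTA ID(s): ", paste(missing, collapse = ", "))
  unused <- setdiff(tax$accession, names(seqs))
  if (length(unused))
    warning("taxonomy rows without FASTA entry ignored: ",
            paste(unused, collapse = ", "))
  tax <- tax[match(names(seqs), tax$accession), , drop = FALSE]

  if (!"synonyms" %in% names(tax)) tax$synonyms <- rep("", nrow(tax))
  tax$synonyms[is.na(tax$synonyms)] <- ""
  # fold per-record synonyms into the map: each listed synonym resolves to
  # the record's canonical species
  for (i in seq_len(nrow(tax))) {
    syn <- trimws(strsplit(tax$synonyms[i], ",")[[1]])
    syn <- syn[nzchar(syn)]
    if (length(syn)) {
      canon <- canonical_species(tax$species[i], synonyms)
      add <- setNames(rep(canon, length(syn)), syn)
      synonyms <- c(synonyms, add[!names(add) %in% names(synonyms)])
    }
  }
  species <- canonical_species(tax$species, synonyms)
  genus <- vapply(strsplit(species, " "), `[[`, "", 1)
  complete <- if ("is_complete_reference" %in% names(tax))
    tolower(tax$is_complete_reference) %in% c("true", "t", "1", "yes")
  else rep(FALSE, nrow(tax))

  upper <- toupper(unname(seqs))
  ok <- nzchar(upper) & is_iupac(upper)
  report <- data.frame(
    accession = names(seqs),
    status = ifelse(ok, "loaded", "rejected"),
    reason = ifelse(ok, "", "non-IUPAC character or empty sequence"),
    stringsAsFactors = FALSE)

  records <- data.frame(
    accession = names(seqs)[ok], species = species[ok], genus = genus[ok],
    family = tax$family[ok], synonyms = tax$synonyms[ok],
    is_complete_reference = complete[ok], sequence = upper[ok],
    stringsAsFactors = FALSE)
  rownames(records) <- NULL
  structure(list(records = records, load_report = report,
                 synonyms = synonyms, amplicons = NULL, inserts = NULL,
                 flags = NULL, groups = NULL),
            class = "barcode_db")
}

#' @export
print.barcode_db <- function(x, ...) {
  cat(sprintf("<barcode_db> %d records, %d species", nrow(x$records),
              length(unique(x$records$species))))
  if (!is.null(x$inserts))
    cat(sprintf(", %d inserts", length(x$inserts)))
  if (!is.null(x$groups))
    cat(sprintf(", %d resolution groups", nrow(x$groups)))
  cat("\n")
  invisible(x)
}

#' Derive amplicon inserts for every database record
#'
#' Runs in-silico PCR on each record and stores the insert: the sequence
#' strictly between the forward-primer 3' end and the reverse-primer binding
#' site (primer-free, matching primer-trimmed reads). Records with no product
#' are flagged non-amplifiable; records with several products inside the
#' length window are flagged ambiguous and keep the shortest. A per-species
#' preferred record is chosen (complete references first, then N-free
#' inserts) and used for grouping and classification.
#'
#' @param db A `barcode_db` from [load_references()].
#' @param assay A [triplex_assay()].
#' @param max_mm Maximum mismatches per primer site.
#' @param length_window Allowed primer-inclusive product length, bp.
#' @return The `barcode_db` with `amplicons`, `inserts` and `flags` populated.
#' @export
build_inserts <- function(db, assay, max_mm = 2, length_window = c(80, 300)) {
  stopifnot(inherits(db, "barcode_db"))
  amps <- digest_database(db, assay, max_mm = max_mm,
                          length_window = length_window)
  acc <- names(amps)
  n_amp <- vapply(amps, nrow, integer(1))
  ambiguous <- n_amp > 1
  if (any(ambiguous))
    message("ambiguous in-silico PCR (multiple products), keeping shortest: ",
            paste(acc[ambiguous], collapse = ", "))
  inserts <- vapply(amps, function(a)
    if (nrow(a) == 0) NA_character_ else a$insert[1], character(1))
  flags <- data.frame(
    accession = acc,
    amplifiable = n_amp > 0,
    ambiguous = ambiguous,
    n_in_insert = !is.na(inserts) & grepl("N", inserts),
    stringsAsFactors = FALSE)

  # reference-quality preference: one record per species for downstream use
  rec <- db$records[match(acc, db$records$accession), , drop = FALSE]
  pref <- rep(FALSE, length(acc))
  for (sp in unique(rec$species)) {
    idx <- which(rec$species == sp & flags$amplifiable)
    if (!length(idx)) next
    score <- rec$is_complete_reference[idx] * 2 + !flags$n_in_insert[idx]
    pref[idx[which.max(score)]] <- TRUE
  }
  flags$preferred <- pref

  db$amplicons <- amps
  db$inserts <- setNames(inserts[!is.na(inserts)], acc[!is.na(inserts)])
  db$flags <- flags
  db$groups <- NULL
  db
}

#' @keywords internal
species_inserts <- function(db) {
  stopifnot(!is.null(db$flags))
  f <- db$flags[db$flags$preferred, , drop = FALSE]
  rec <- db$records[match(f$accession, db$records$accession), , drop = FALSE]
  setNames(unname(db$inserts[f$accession]), rec$species)
}

#' Species-resolution groups from insert identity
#'
#' Partitions species into equivalence classes under exact identity of their
#' (preferred) amplicon inserts. Singleton groups are labelled with the
#' species name; multi-member groups whose members share a genus are labelled
#' `"<Genus> spp."`; cross-genus groups get a slash-joined member list.
#' Species without inserts are gathered into one `"non-amplifiable"` class.
#'
#' @param db A `barcode_db` after [build_inserts()].
#' @return A data.frame with columns `label`, `n`, `insert` and list-column
#'   `members`; [build_db()] stores it on the database as `$groups`.
#' @export
resolution_groups <- function(db) {
  stopifnot(inherits(db, "barcode_db"), !is.null(db$inserts))
  ins <- species_inserts(db)
  groups <- list()
  if (length(ins)) {
    for (key in unique(unname(ins))) {
      members <- sort(names(ins)[ins == key])
      genus <- unique(vapply(strsplit(members, " "), `[[`, "", 1))
      label <- if (length(members) == 1) members
      else if (length(genus) == 1) paste(genus, "spp.")
      else paste(members, collapse = "/")
      groups[[length(groups) + 1]] <- data.frame(
        label = label, n = length(members), insert = key,
        members = I(list(members)), stringsAsFactors = FALSE)
    }
  }
  no_ins <- sort(setdiff(unique(db$records$species), names(ins)))
  if (length(no_ins))
    groups[[length(groups) + 1]] <- data.frame(
      label = "non-amplifiable", n = length(no_ins), insert = NA_character_,
      members = I(list(no_ins)), stringsAsFactors = FALSE)
  out <- do.call(rbind, groups)
  out <- out[order(out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a complete barcode database in one call
#'
#' [load_references()] + [build_inserts()] + [resolution_groups()].
#'
#' @inheritParams load_references
#' @inheritParams build_inserts
#' @return A `barcode_db` with records, inserts, flags and groups populated.
#' @export
build_db <- function(fasta_path, taxonomy_path, assay = default_assay(),
                     max_mm = 2, length_window = c(80, 300),
                     synonyms = default_synonyms()) {
  db <- load_references(fasta_path, taxonomy_path, synonyms = synonyms)
  db <- build_inserts(db, assay, max_mm = max_mm,
                      length_window = length_window)
  db$groups <- resolution_groups(db)
  db
}

#' Map each species to its resolution-group label
#'
#' @param db A `barcode_db` with groups built.
#' @return Named character vector `species -> label`.
#' @export
species_labels <- function(db) {
  stopifnot(!is.null(db$groups))
  g <- db$groups
  out <- character(0)
  for (i in seq_len(nrow(g)))
    out[g$members[[i]]] <- g$label[i]
  out
}

#' Write a database bundle to disk
#'
#' Emits `references.fasta` and `taxonomy.tsv` (sufficient to reload the
#' database), plus derived views: `inserts.fasta` (preferred insert per
#' species), `groups.tsv` and `load_report.txt`.
#'
#' @param db A built `barcode_db`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_db <- function(db, dir) {
  stopifnot(inherits(db, "barcode_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(setNames(db$records$sequence, db$records$accession),
              file.path(dir, "references.fasta"))
  tax <- db$records[, c("accession", "species", "genus", "family",
                        "synonyms", "is_complete_reference")]
  write.table(tax, file.path(dir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(db$inserts)) {
    ins <- species_inserts(db)
    write_fasta(setNames(unname(ins), gsub(" ", "_", names(ins))),
                file.path(dir, "inserts.fasta"))
  }
  if (!is.null(db$groups)) {
    g <- data.frame(label = db$groups$label, n = db$groups$n,
                    members = vapply(db$groups$members, paste,
                                     character(1), collapse = ";"))
    write.table(g, file.path(dir, "groups.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  writeLines(sprintf("%s\t%s\t%s", db$load_report$accession,
                     db$load_report$status, db$load_report$reason),
             file.path(dir, "load_report.txt"))
  invisible(dir)
}

#' Reload a database bundle written by [write_db()]
#'
#' @param dir Bundle directory.
#' @param assay,max_mm,length_window Passed to [build_db()].
#' @return A rebuilt `barcode_db`.
#' @export
read_db <- function(dir, assay = default_assay(), max_mm = 2,
                    length_window = c(80, 300)) {
  build_db(file.path(dir, "references.fasta"),
           file.path(dir, "taxonomy.tsv"),
           assay = assay, max_mm = max_mm, length_window = length_window)
}
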