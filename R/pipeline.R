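# The amplicon analysis workflow, re-implemented: merge read pairs, trim the
# target-specific primers from both ends, collapse identical sequences, and
# classify representatives against the customized database by edit-distance
# identity with collapse to the species-resolution group where needed.

#' Merge read pairs by ungapped overlap
#'
#' Finds the maximal-scoring ungapped overlap between R1 and the reverse
#' complement of R2 among offsets with overlap `>= min_overlap` and mismatch
#' fraction `<= max_mismatch_frac`. Disagreements resolve to the base with
#' the higher quality; ties go to R1. Rejections are values, not errors.
#'
#' @param r1,r2 Character vectors of read sequences (equal length vectors).
#' @param q1,q2 Matching Phred+33 quality strings (default: constant, so all
#'   ties resolve to R1).
#' @param min_overlap Minimum overlap length in bp.
#' @param max_mismatch_frac Maximum mismatch fraction inside the overlap.
#' @return A data.frame with columns `merged` (NA when rejected) and `reason`
#'   (NA when merged).
#' @export
merge_pairs <- function(r1, r2, q1 = NULL, q2 = NULL, min_overlap = 20,
                        max_mismatch_frac = 0.1) {
  stopifnot(length(r1) == length(r2))
  if (is.null(q1)) q1 <- strrep("I", nchar(r1))
  if (is.null(q2)) q2 <- strrep("I", nchar(r2))
  b <- revcomp(toupper(r2))
  qb <- vapply(strsplit(q2, ""), function(x) paste(rev(x), collapse = ""),
               character(1))
  res <- cpp_merge_pairs(toupper(r1), q1, b, qb, as.integer(min_overlap),
                         max_mismatch_frac)
  data.frame(merged = as.character(res$merged),
             reason = as.character(res$reason), stringsAsFactors = FALSE)
}

#' Trim target-specific primers from both ends of merged reads
#'
#' Requires a forward-primer match at the 5' end and a reverse-primer
#' reverse-complement match at the 3' end from the same family primer set,
#' each within `max_mm` mismatches. The flipped orientation is checked before
#' rejecting. Vectorized over sequences.
#'
#' @param seqs Character vector of merged sequences.
#' @param assay A [triplex_assay()].
#' @param max_mm Maximum mismatches per primer end.
#' @return A data.frame with columns `insert` (NA when rejected), `family`
#'   and `reason` (one of `no-forward`, `no-reverse`, `family-conflict`).
#' @export
trim_primers <- function(seqs, assay, max_mm = 2) {
  stopifnot(inherits(assay, "triplex_assay"))
  seqs <- toupper(seqs)
  res <- trim_oriented(seqs, assay, max_mm)
  flip <- which(is.na(res$insert))
  if (length(flip)) {
    res2 <- trim_oriented(revcomp(seqs[flip]), assay, max_mm)
    better <- which(!is.na(res2$insert))
    if (length(better)) res[flip[better], ] <- res2[better, ]
  }
  res
}

# single-orientation trimming over a vector of sequences
#' @keywords internal
trim_oriented <- function(seqs, assay, max_mm) {
  n <- length(seqs)
  out <- data.frame(insert = rep(NA_character_, n),
                    family = rep(NA_character_, n),
                    reason = rep(NA_character_, n), stringsAsFactors = FALSE)
  if (n == 0) return(out)
  # best forward / reverse end-match per family
  fwd_mm <- list(); fwd_len <- list()
  rev_mm <- list(); rev_len <- list()
  for (fam in names(assay$sets)) {
    set <- assay$sets[[fam]]
    fm <- rep(NA_integer_, n); fl <- rep(NA_integer_, n)
    for (p in set$forwards) {
      mm <- cpp_end_mismatch(seqs, p$sequence, at_start = TRUE)
      upd <- !is.na(mm) & mm <= max_mm & (is.na(fm) | mm < fm)
      fm[upd] <- mm[upd]; fl[upd] <- nchar(p$sequence)
    }
    rm_ <- rep(NA_integer_, n); rl <- rep(NA_integer_, n)
    for (p in set$reverses) {
      mm <- cpp_end_mismatch(seqs, revcomp(p$sequence), at_start = FALSE)
      upd <- !is.na(mm) & mm <= max_mm & (is.na(rm_) | mm < rm_)
      rm_[upd] <- mm[upd]; rl[upd] <- nchar(p$sequence)
    }
    fwd_mm[[fam]] <- fm; fwd_len[[fam]] <- fl
    rev_mm[[fam]] <- rm_; rev_len[[fam]] <- rl
  }
  fams <- names(assay$sets)
  fwd_any <- Reduce(`|`, lapply(fwd_mm, function(x) !is.na(x)))
  rev_any <- Reduce(`|`, lapply(rev_mm, function(x) !is.na(x)))
  for (i in seq_len(n)) {
    both <- fams[vapply(fams, function(f)
      !is.na(fwd_mm[[f]][i]) && !is.na(rev_mm[[f]][i]), logical(1))]
    if (length(both)) {
      tot <- vapply(both, function(f) fwd_mm[[f]][i] + rev_mm[[f]][i],
                    numeric(1))
      f <- both[which.min(tot)]
      L <- nchar(seqs[i])
      ins_start <- fwd_len[[f]][i] + 1
      ins_end <- L - rev_len[[f]][i]
      if (ins_end >= ins_start) {
        out$insert[i] <- substr(seqs[i], ins_start, ins_end)
        out$family[i] <- f
        next
      }
    }
    out$reason[i] <- if (!fwd_any[i]) "no-forward"
    else if (!rev_any[i]) "no-reverse"
    else "family-conflict"
  }
  out
}

#' Dereplicate identical sequences
#'
#' Collapses exactly identical sequences (after uppercasing) into one
#' representative with a count; clusters are sorted by count descending then
#' lexicographically.
#'
#' @param inserts Character vector of sequences.
#' @return A data.frame with columns `representative` and `count`.
#' @export
dereplicate <- function(inserts) {
  if (length(inserts) == 0)
    return(data.frame(representative = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(toupper(inserts))
  out <- data.frame(representative = names(tab),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$representative), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify dereplicated representatives against the database
#'
#' Identity against each database insert is
#' `1 - editDistance / max(lengths)` (global Levenshtein). The best identity
#' wins; below `min_identity` the representative is `"unassigned"`. When
#' several species tie at the best identity, the label collapses to their
#' common resolution group if they share one, else to `"<Genus> spp."` if
#' they share a genus, else `"ambiguous"`.
#'
#' @param clusters A data.frame from [dereplicate()] (columns
#'   `representative`, `count`).
#' @param db A built `barcode_db` (inserts and groups populated).
#' @param min_identity Minimum identity for assignment, default 0.97.
#' @return The clusters with added `label` and `identity` columns.
#' @export
classify <- function(clusters, db, min_identity = 0.97) {
  stopifnot(inherits(db, "barcode_db"), !is.null(db$inserts),
            !is.null(db$groups))
  ins <- species_inserts(db)
  if (length(ins) == 0) stop("database has no inserts to classify against")
  labels <- species_labels(db)
  out <- clusters
  out$label <- character(nrow(out))
  out$identity <- numeric(nrow(out))
  if (nrow(out) == 0) return(out)
  d <- adist(out$representative, unname(ins))
  reps_len <- nchar(out$representative)
  ins_len <- nchar(unname(ins))
  for (i in seq_len(nrow(out))) {
    id <- 1 - d[i, ] / pmax(reps_len[i], ins_len)
    best <- max(id)
    if (best < min_identity) {
      out$label[i] <- "unassigned"
      out$identity[i] <- best
      next
    }
    tied <- names(ins)[id == best]
    out$identity[i] <- best
    if (length(tied) == 1) {
      out$label[i] <- labels[[tied]]
    } else {
      grp <- unique(labels[tied])
      if (length(grp) == 1) {
        out$label[i] <- grp
      } else {
        genus <- unique(vapply(strsplit(tied, " "), `[[`, "", 1))
        out$label[i] <- if (length(genus) == 1) paste(genus, "spp.")
        else "ambiguous"
      }
    }
  }
  out
}

#' Default pipeline parameters
#'
#' @param max_mm Mismatches tolerated per primer end during trimming.
#' @param min_identity Classification identity threshold.
#' @param min_overlap,max_mismatch_frac Merge parameters.
#' @param report_threshold_percent Detection threshold: a label is "detected"
#'   at or above this percentage of reads passing the workflow.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(max_mm = 2, min_identity = 0.97, min_overlap = 20,
                            max_mismatch_frac = 0.1,
                            report_threshold_percent = 1.0) {
  list(max_mm = max_mm, min_identity = min_identity,
       min_overlap = min_overlap, max_mismatch_frac = max_mismatch_frac,
       report_threshold_percent = report_threshold_percent)
}

#' Run the full analysis workflow on one sample
#'
#' merge -> trim -> dereplicate -> classify -> tabulate. Deterministic for
#' fixed inputs.
#'
#' @param fastq_r1,fastq_r2 Paired FASTQ paths (Phred+33).
#' @param db A built `barcode_db`.
#' @param assay A [triplex_assay()].
#' @param params See [pipeline_params()].
#' @param sample_id Sample identifier for the report.
#' @return A `sample_report` object: `sample_id`, `total_raw_reads`,
#'   `reads_passing_workflow`, `table` (per label: reads_assigned,
#'   percent_assigned, detected), `assignments` (per cluster), `rejects`
#'   (reason counts, all categories present).
#' @export
run_sample <- function(fastq_r1, fastq_r2, db, assay = default_assay(),
                       params = pipeline_params(), sample_id = "sample") {
  for (fp in c(fastq_r1, fastq_r2))
    if (!file.exists(fp)) stop("FASTQ not found: ", fp)
  f1 <- read_fastq(fastq_r1)
  f2 <- read_fastq(fastq_r2)
  if (length(f1$seq) != length(f2$seq))
    stop("R1/R2 read counts differ (", length(f1$seq), " vs ",
         length(f2$seq), ")")
  n_raw <- length(f1$seq)

  reject_reasons <- c("no-overlap", "no-forward", "no-reverse",
                      "family-conflict", "unassigned")
  rejects <- setNames(integer(length(reject_reasons)), reject_reasons)

  if (n_raw == 0) {
    merged <- character(0)
  } else {
    m <- merge_pairs(f1$seq, f2$seq, f1$qual, f2$qual,
                     min_overlap = params$min_overlap,
                     max_mismatch_frac = params$max_mismatch_frac)
    bad <- table(m$reason[!is.na(m$reason)])
    rejects[names(bad)] <- rejects[names(bad)] + as.integer(bad)
    merged <- m$merged[!is.na(m$merged)]
  }

  # trim on dereplicated merged sequences (identical reads trim identically)
  dmerged <- dereplicate(merged)
  tr <- trim_primers(dmerged$representative, assay, max_mm = params$max_mm)
  bad <- tapply(dmerged$count[!is.na(tr$reason)], tr$reason[!is.na(tr$reason)],
                sum)
  if (length(bad)) rejects[names(bad)] <- rejects[names(bad)] + as.integer(bad)
  keep <- !is.na(tr$insert)
  clusters <- data.frame(representative = tr$insert[keep],
                         count = dmerged$count[keep],
                         stringsAsFactors = FALSE)
  clusters <- if (nrow(clusters)) {
    agg <- tapply(clusters$count, clusters$representative, sum)
    d <- data.frame(representative = names(agg), count = as.integer(agg),
                    stringsAsFactors = FALSE)
    d[order(-d$count, d$representative), , drop = FALSE]
  } else clusters
  rownames(clusters) <- NULL
  passing <- sum(clusters$count)

  assignments <- if (nrow(clusters)) {
    classify(clusters, db, min_identity = params$min_identity)
  } else cbind(clusters, label = character(0), identity = numeric(0))
  rejects["unassigned"] <-
    sum(assignments$count[assignments$label == "unassigned"])

  assigned <- assignments[assignments$label != "unassigned", , drop = FALSE]
  tab <- if (nrow(assigned)) {
    agg <- tapply(assigned$count, assigned$label, sum)
    data.frame(label = names(agg), reads_assigned = as.integer(agg),
               stringsAsFactors = FALSE)
  } else data.frame(label = character(0), reads_assigned = integer(0),
                    stringsAsFactors = FALSE)
  tab$percent_assigned <- if (passing > 0)
    round(100 * tab$reads_assigned / passing, 2) else numeric(nrow(tab))
  tab$detected <- tab$percent_assigned >= params$report_threshold_percent
  tab <- tab[order(-tab$reads_assigned, tab$label), , drop = FALSE]
  rownames(tab) <- NULL

  structure(list(sample_id = sample_id, total_raw_reads = n_raw,
                 reads_passing_workflow = passing, table = tab,
                 assignments = assignments,
                 rejects = data.frame(reason = names(rejects),
                                      count = as.integer(rejects),
                                      stringsAsFactors = FALSE),
                 params = params),
            class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("<sample_report> %s\n", x$sample_id))
  cat(sprintf("  raw read pairs:          %d\n", x$total_raw_reads))
  cat(sprintf("  reads passing workflow:  %d\n", x$reads_passing_workflow))
  if (nrow(x$table)) {
    for (i in seq_len(nrow(x$table)))
      cat(sprintf("  %-35s %8d  %6.2f%%%s\n", x$table$label[i],
                  x$table$reads_assigned[i], x$table$percent_assigned[i],
                  if (x$table$detected[i]) "  *" else ""))
    cat("  (* detected at >= ",
        x$params$report_threshold_percent, "% of reads passing)\n", sep = "")
  } else cat("  no assignments\n")
  invisible(x)
}

#' Write a sample report as a TSV with the published column layout
#'
#' @param report A `sample_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "sample_report"))
  df <- data.frame(
    `Sample ID` = report$sample_id,
    `Species Identified` = report$table$label,
    `Total Number of Raw Reads` = report$total_raw_reads,
    `Total Number of Reads Passing the Workflow` =
      report$reads_passing_workflow,
    `Number of Reads Assigned Correctly` = report$table$reads_assigned,
    `Percentage of Reads Assigned Correctly (%)` =
      report$table$percent_assigned,
    check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Percentage of reads assigned, as reported
#'
#' `100 * assigned / passing`, rounded to 2 decimals — the published
#' percentage column recomputed from its count columns.
#'
#' @param assigned Reads assigned to the label.
#' @param passing Reads passing the workflow (denominator).
#' @return Percentage rounded to 2 decimals.
#' @export
#' @examples
#' percent_assigned(57058, 58069)  # 98.26
percent_assigned <- function(assigned, passing) {
  round(100 * assigned / passing, 2)
}
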