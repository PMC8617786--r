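# The triplex primer system: three family-specific primer sets (mussels need
# one forward + two reverse primers; scallops and oysters one pair each),
# seven target-specific primers in total, plus the two Illumina overhang
# adapters prepended during library preparation.

#' Construct a primer
#'
#' @param name Primer name, e.g. `"For_Mu"`.
#' @param sequence 5'->3' DNA sequence (IUPAC alphabet), length >= 15.
#' @param direction `"forward"` or `"reverse"`.
#' @param family_target Target family: `"Mytilidae"`, `"Pectinidae"` or
#'   `"Ostreidae"` (free-form strings are allowed for user assays).
#' @param concentration_uM Final PCR concentration in µM (metadata only).
#' @return A `primer` object.
#' @export
primer <- function(name, sequence, direction = c("forward", "reverse"),
                   family_target, concentration_uM = 0.2) {
  direction <- match.arg(direction)
  sequence <- toupper(sequence)
  stopifnot(is.character(name), nzchar(name),
            is.character(family_target), nzchar(family_target))
  if (!is_iupac(sequence))
    stop("primer '", name, "' contains non-IUPAC characters")
  if (nchar(sequence) < 15)
    stop("primer '", name, "' is shorter than 15 nt")
  structure(list(name = name, sequence = sequence, direction = direction,
                 family_target = family_target,
                 concentration_uM = concentration_uM),
            class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s (%s, %s) %s [%g uM]\n", x$name, x$direction,
              x$family_target, x$sequence, x$concentration_uM))
  invisible(x)
}

#' Construct a family primer set
#'
#' @param forwards,reverses Lists of [primer()] objects (at least one each);
#'   all must share the set's target family.
#' @param family Target family name.
#' @return A `primer_set` object.
#' @export
primer_set <- function(forwards, reverses, family) {
  stopifnot(length(forwards) >= 1, length(reverses) >= 1)
  all_p <- c(forwards, reverses)
  ok <- vapply(all_p, function(p) inherits(p, "primer") &&
                 identical(p$family_target, family), logical(1))
  if (!all(ok)) stop("all primers in a set must target family '", family, "'")
  dirs <- vapply(forwards, `[[`, "", "direction")
  if (!all(dirs == "forward")) stop("forwards must have direction 'forward'")
  dirs <- vapply(reverses, `[[`, "", "direction")
  if (!all(dirs == "reverse")) stop("reverses must have direction 'reverse'")
  structure(list(forwards = forwards, reverses = reverses, family = family),
            class = "primer_set")
}

#' Construct a triplex assay
#'
#' @param sets List of three [primer_set()] objects (one per family).
#' @param overhang_forward,overhang_reverse Illumina overhang adapter
#'   sequences prepended to forward/reverse target-specific primers.
#' @param annealing_temp_C,cycles PCR metadata (not used computationally).
#' @return A `triplex_assay` object.
#' @export
triplex_assay <- function(sets, overhang_forward, overhang_reverse,
                          annealing_temp_C = 62, cycles = 25) {
  stopifnot(is.list(sets),
            all(vapply(sets, inherits, logical(1), "primer_set")))
  names(sets) <- vapply(sets, `[[`, "", "family")
  structure(list(sets = sets,
                 overhang_forward = toupper(overhang_forward),
                 overhang_reverse = toupper(overhang_reverse),
                 annealing_temp_C = annealing_temp_C, cycles = cycles),
            class = "triplex_assay")
}

#' @export
print.triplex_assay <- function(x, ...) {
  np <- nrow(assay_primers(x))
  cat(sprintf("<triplex_assay> %d families, %d target-specific primers, %g C, %d cycles\n",
              length(x$sets), np, x$annealing_temp_C, x$cycles))
  for (s in x$sets)
    cat(sprintf("  %s: %d forward + %d reverse\n", s$family,
                length(s$forwards), length(s$reverses)))
  invisible(x)
}

#' The packaged triplex assay
#'
#' The seven published target-specific primers (three forward, four reverse)
#' for Mytilidae, Pectinidae and Ostreidae, with the Illumina overhang
#' adapters, annealing temperature 62 °C and 25 cycles. The published primer
#' table labels every row `For_Mu`/`Rev_Mu`; here scallop and oyster primers
#' are renamed `For_Sc`/`Rev_Sc` and `For_Oy`/`Rev_Oy` with sequences kept
#' verbatim.
#'
#' @return A [triplex_assay()] object.
#' @export
#' @examples
#' default_assay()
default_assay <- function() {
  mussel <- primer_set(
    forwards = list(
      primer("For_Mu", "CCTTTTGCATAAGGGTTTTTCAAG", "forward", "Mytilidae",
             concentration_uM = 0.4)),
    reverses = list(
      primer("Rev1_Mu", "CGAATAGTATCTAGCCGCCATTC", "reverse", "Mytilidae"),
      primer("Rev2_Mu", "GCAAATAGCATATCACTTTCACCTC", "reverse", "Mytilidae")),
    family = "Mytilidae")
  scallop <- primer_set(
    forwards = list(
      primer("For_Sc", "TGCTAAGGTAGCTAAATTATGGCC", "forward", "Pectinidae")),
    reverses = list(
      primer("Rev_Sc", "CTTCACGGGGTCTTCTCGTC", "reverse", "Pectinidae")),
    family = "Pectinidae")
  oyster <- primer_set(
    forwards = list(
      primer("For_Oy", "GGTAGCGAAATTCCTTGCCTT", "forward", "Ostreidae")),
    reverses = list(
      primer("Rev_Oy", "AAAGTTGCACGGGGTCTT", "reverse", "Ostreidae")),
    family = "Ostreidae")
  triplex_assay(
    sets = list(mussel, scallop, oyster),
    overhang_forward = "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
    overhang_reverse = "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG",
    annealing_temp_C = 62, cycles = 25)
}

#' Flatten an assay to a primer table
#'
#' @param assay A [triplex_assay()].
#' @return A data.frame with one row per target-specific primer: name,
#'   sequence, direction, family, concentration_uM.
#' @export
assay_primers <- function(assay) {
  stopifnot(inherits(assay, "triplex_assay"))
  rows <- lapply(assay$sets, function(s) {
    lapply(c(s$forwards, s$reverses), function(p)
      data.frame(name = p$name, sequence = p$sequence,
                 direction = p$direction, family = p$family_target,
                 concentration_uM = p$concentration_uM,
                 stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  out
}

#' Count IUPAC-aware mismatches between a primer and a window
#'
#' A window base matches when it is a concrete nucleotide inside the primer
#' base's IUPAC expansion (`N` in the primer matches everything; ambiguity
#' codes in the window never match).
#'
#' @param primer_seq Primer sequence (IUPAC).
#' @param window Template window of equal length.
#' @return Integer mismatch count.
#' @export
#' @examples
#' mismatch_count("NNNN", "ACGT")  # 0
mismatch_count <- function(primer_seq, window) {
  cpp_mismatch_count(toupper(primer_seq), toupper(window))
}

#' Find primer binding sites on a template
#'
#' Searches both orientations: the primer as-is on the plus strand (reported
#' strand `"+"`) and its reverse complement on the plus strand (reported
#' strand `"-"`). A site requires at most `max_mm` mismatches overall and an
#' exact match over the `anchor` bases at the primer's 3' end, mimicking the
#' sensitivity of polymerase extension to 3'-terminal mismatches.
#'
#' @param template Template sequence (uppercase DNA).
#' @param primer A [primer()] object.
#' @param max_mm Maximum number of mismatches outside the 3' anchor.
#' @param anchor Number of 3'-terminal bases that must match exactly.
#' @param template_id Identifier recorded in the result.
#' @return A data.frame of binding sites: template_id, primer_name, strand,
#'   start, end (0-based, half-open, plus-strand coordinates), mismatches.
#' @export
find_binding_sites <- function(template, primer, max_mm = 2, anchor = 3,
                               template_id = "template") {
  stopifnot(inherits(primer, "primer"))
  template <- toupper(template)
  m <- nchar(primer$sequence)
  plus <- cpp_find_sites(template, primer$sequence, max_mm,
                         anchor_at_end = TRUE, anchor_len = anchor)
  rcpat <- revcomp(primer$sequence)
  minus <- cpp_find_sites(template, rcpat, max_mm,
                          anchor_at_end = FALSE, anchor_len = anchor)
  out <- rbind(
    if (nrow(plus)) data.frame(strand = "+", start = plus$start,
                               mismatches = plus$mismatches),
    if (nrow(minus)) data.frame(strand = "-", start = minus$start,
                                mismatches = minus$mismatches))
  if (is.null(out) || nrow(out) == 0)
    return(data.frame(template_id = character(0), primer_name = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0)))
  out <- data.frame(template_id = template_id, primer_name = primer$name,
                    strand = out$strand, start = out$start,
                    end = out$start + m, mismatches = out$mismatches,
                    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Wallace-rule melting temperature
#'
#' `Tm = 2 (A+T) + 4 (G+C)` in degrees Celsius; suitable for short
#' oligonucleotides and used here as a quick primer QC statistic.
#'
#' @param seq DNA sequence containing only A, C, G, T.
#' @return Melting temperature in °C.
#' @export
#' @examples
#' tm_wallace("AAAA")  # 8
tm_wallace <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq))
    stop("tm_wallace() requires unambiguous bases (A/C/G/T only)")
  bases <- strsplit(seq, "")[[1]]
  at <- sum(bases %in% c("A", "T"))
  gc <- sum(bases %in% c("G", "C"))
  2 * at + 4 * gc
}

#' Self-complementarity score
#'
#' Length of the longest run of contiguous complementary bases between a
#' sequence and its own reverse complement over all ungapped offsets — a
#' simple self-dimer/hairpin indicator. Advisory only; the score never blocks
#' an assay.
#'
#' @param seq DNA sequence containing only A, C, G, T.
#' @return Integer score (0 = no self-complementary run).
#' @export
#' @examples
#' self_complement_score("ACGT")  # 4 (palindrome)
self_complement_score <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq))
    stop("self_complement_score() requires unambiguous bases")
  s <- strsplit(seq, "")[[1]]
  r <- strsplit(revcomp(seq), "")[[1]]
  n <- length(s)
  best <- 0L
  for (off in (-(n - 1)):(n - 1)) {
    i <- max(1, 1 + off); j <- max(1, 1 - off)
    run <- 0L
    while (i <= n && j <= n) {
      if (s[i] == r[j]) {
        run <- run + 1L
        if (run > best) best <- run
      } else run <- 0L
      i <- i + 1L; j <- j + 1L
    }
  }
  best
}

#' Full primer sequence including the Illumina overhang adapter
#'
#' @param primer A [primer()] belonging to `assay`.
#' @param assay A [triplex_assay()].
#' @return The adapter-prefixed 5'->3' sequence.
#' @export
with_overhang <- function(primer, assay) {
  stopifnot(inherits(primer, "primer"), inherits(assay, "triplex_assay"))
  tab <- assay_primers(assay)
  if (!any(tab$name == primer$name & tab$sequence == primer$sequence))
    stop("primer '", primer$name, "' is not part of the assay")
  oh <- if (primer$direction == "forward") assay$overhang_forward
        else assay$overhang_reverse
  paste0(oh, primer$sequence)
}

#' Read a triplex assay from a YAML config file
#'
#' The file holds `overhang_forward`, `overhang_reverse`, optional
#' `annealing_temp_C`/`cycles`, and a `primers` list of records with name,
#' sequence, direction, family and concentration_uM.
#'
#' @param path Path to the YAML file.
#' @return A [triplex_assay()].
#' @export
read_assay <- function(path) {
  cfg <- yaml::read_yaml(path)
  prim <- lapply(cfg$primers, function(p)
    primer(p$name, p$sequence, p$direction, p$family,
           concentration_uM = if (is.null(p$concentration_uM)) 0.2
                              else p$concentration_uM))
  fams <- unique(vapply(prim, `[[`, "", "family_target"))
  sets <- lapply(fams, function(f) {
    ps <- prim[vapply(prim, function(p) p$family_target == f, logical(1))]
    fwd <- ps[vapply(ps, function(p) p$direction == "forward", logical(1))]
    rev <- ps[vapply(ps, function(p) p$direction == "reverse", logical(1))]
    primer_set(fwd, rev, f)
  })
  triplex_assay(sets, cfg$overhang_forward, cfg$overhang_reverse,
                annealing_temp_C = cfg$annealing_temp_C %||% 62,
                cycles = cfg$cycles %||% 25)
}

#' Write a triplex assay to a YAML config file
#'
#' @param assay A [triplex_assay()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay <- function(assay, path) {
  tab <- assay_primers(assay)
  cfg <- list(
    overhang_forward = assay$overhang_forward,
    overhang_reverse = assay$overhang_reverse,
    annealing_temp_C = assay$annealing_temp_C,
    cycles = assay$cycles,
    primers = lapply(seq_len(nrow(tab)), function(i)
      list(name = tab$name[i], sequence = tab$sequence[i],
           direction = tab$direction[i], family = tab$family[i],
           concentration_uM = tab$concentration_uM[i])))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
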