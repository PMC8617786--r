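# In-silico PCR: pair forward and reverse binding sites of each family primer
# set into predicted products. Coordinates are 0-based half-open on the plus
# strand of the stored template; product sequences are always reported in
# canonical orientation (forward primer at the 5' end).

#' Predict triplex PCR amplicons on a template
#'
#' For every family primer set, every pairing of a forward-primer site with a
#' downstream reverse-primer site whose product length falls inside
#' `length_window` yields one amplicon. The reverse-complement orientation of
#' the template is scanned as well; such products are reported on plus-strand
#' coordinates with `orientation = "-"` and a canonicalized sequence.
#'
#' @param template Template DNA (character) or a single row of a barcode DB's
#'   `records` table.
#' @param assay A [triplex_assay()].
#' @param max_mm Maximum mismatches per primer site (3' anchor must be exact).
#' @param length_window Numeric `c(min, max)` allowed primer-inclusive product
#'   length in bp.
#' @param anchor Exact-match 3'-terminal bases required per site.
#' @param template_id Identifier recorded in results.
#' @return A data.frame of amplicons sorted by length then start: template_id,
#'   family, forward, reverse, orientation, start, end, length, mismatches,
#'   sequence (canonical), insert (primer-free interior, canonical).
#' @export
predict_amplicons <- function(template, assay, max_mm = 2,
                              length_window = c(80, 300), anchor = 3,
                              template_id = "template") {
  stopifnot(inherits(assay, "triplex_assay"),
            length(length_window) == 2, length_window[1] < length_window[2])
  if (is.data.frame(template)) {
    template_id <- template$accession[1]
    template <- template$sequence[1]
  }
  template <- toupper(template)
  empty <- data.frame(template_id = character(0), family = character(0),
                      forward = character(0), reverse = character(0),
                      orientation = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      mismatches = integer(0), sequence = character(0),
                      insert = character(0), stringsAsFactors = FALSE)
  out <- list()
  for (set in assay$sets) {
    fsites <- do.call(rbind, lapply(set$forwards, find_binding_sites,
                                    template = template, max_mm = max_mm,
                                    anchor = anchor, template_id = template_id))
    rsites <- do.call(rbind, lapply(set$reverses, find_binding_sites,
                                    template = template, max_mm = max_mm,
                                    anchor = anchor, template_id = template_id))
    if (is.null(fsites) || is.null(rsites) ||
        nrow(fsites) == 0 || nrow(rsites) == 0) next
    for (i in seq_len(nrow(fsites))) {
      f <- fsites[i, ]
      for (j in seq_len(nrow(rsites))) {
        r <- rsites[j, ]
        if (f$strand == "+" && r$strand == "-" && r$start >= f$end) {
          # plus-orientation product: forward footprint ... reverse footprint
          len <- r$end - f$start
          if (len < length_window[1] || len > length_window[2]) next
          seq <- substr(template, f$start + 1, r$end)
          ins <- substr(template, f$end + 1, r$start)
          out[[length(out) + 1]] <- data.frame(
            template_id = template_id, family = set$family,
            forward = f$primer_name, reverse = r$primer_name,
            orientation = "+", start = f$start, end = r$end, length = len,
            mismatches = f$mismatches + r$mismatches,
            sequence = seq, insert = ins, stringsAsFactors = FALSE)
        } else if (f$strand == "-" && r$strand == "+" && f$start >= r$end) {
          # product lies on the reverse orientation of the template
          len <- f$end - r$start
          if (len < length_window[1] || len > length_window[2]) next
          seq <- revcomp(substr(template, r$start + 1, f$end))
          ins <- revcomp(substr(template, r$end + 1, f$start))
          out[[length(out) + 1]] <- data.frame(
            template_id = template_id, family = set$family,
            forward = f$primer_name, reverse = r$primer_name,
            orientation = "-", start = r$start, end = f$end, length = len,
            mismatches = f$mismatches + r$mismatches,
            sequence = seq, insert = ins, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$length, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' In-silico PCR over a whole barcode database
#'
#' @param db A barcode DB from [load_references()].
#' @param assay A [triplex_assay()].
#' @inheritParams predict_amplicons
#' @return Named list (sorted by accession) of per-record amplicon tables as
#'   returned by [predict_amplicons()]; empty table = non-amplifiable.
#' @export
digest_database <- function(db, assay, max_mm = 2, length_window = c(80, 300),
                            anchor = 3) {
  stopifnot(inherits(db, "barcode_db"))
  acc <- sort(db$records$accession)
  out <- lapply(acc, function(a) {
    rec <- db$records[db$records$accession == a, , drop = FALSE]
    predict_amplicons(rec$sequence, assay, max_mm = max_mm,
                      length_window = length_window, anchor = anchor,
                      template_id = a)
  })
  setNames(out, acc)
}
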