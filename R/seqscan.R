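# EF-hand loop detection and classification from sequence.

#' Build a sequence record table
#'
#' @param id Character identifier(s).
#' @param residues One-letter amino-acid string(s) (20 standard codes; `X`
#'   allowed as a wildcard that fails every constrained position).
#' @param numbering_offset Author residue number of the first residue of each
#'   sequence (e.g. 743 for the alpha-actinin-1 CaMD construct), so reported
#'   loop starts use author numbering.
#' @return A tibble with columns `id`, `residues`, `numbering_offset`.
#' @export
#' @examples
#' sequence_record("toy", "AADKDGDGTITTKEAA", numbering_offset = 100)
sequence_record <- function(id, residues, numbering_offset = 1L) {
  residues <- toupper(residues)
  bad <- !grepl(paste0("^[", paste(c(AA_STANDARD, "X"), collapse = ""), "]*$"),
                residues)
  if (any(bad)) {
    stop_input(paste0("non-standard residue codes in: ",
                      paste(id[bad], collapse = ", ")))
  }
  tibble(id = unname(as.character(id)), residues = unname(residues),
         numbering_offset = unname(as.integer(numbering_offset)))
}

#' Read a FASTA file into a sequence record table
#'
#' @param path FASTA file (single or multi-record).
#' @inheritParams sequence_record
#' @return A tibble as from [sequence_record()].
#' @export
read_fasta <- function(path, numbering_offset = 1L) {
  ss <- Biostrings::readAAStringSet(path)
  sequence_record(sub("\\s.*$", "", names(ss)), as.character(ss),
                  numbering_offset)
}

#' Write sequence records to FASTA
#'
#' @param seqs Tibble from [sequence_record()].
#' @param path Output file path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(setNames(seqs$residues, seqs$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Evaluate one 12-residue window against a rule set. Returns a tibble of
# per-position calls. `X` in the sequence fails any constrained position.
evaluate_loop <- function(loop_seq, rules) {
  res <- strsplit(loop_seq, "")[[1]]
  tibble(
    label = rules$label,
    position = rules$position,
    residue = res[rules$position],
    pass = map2(rules$allowed, rules$position, function(allowed, pos) {
      if (all(is.na(allowed))) TRUE else res[pos] %in% allowed
    }) |> unlist() |> unname()
  )
}

#' Scan sequences for canonical EF-hand calcium-binding loops
#'
#' In `window` mode every 12-residue window whose first residue satisfies the
#' X(1) rule is evaluated against all coordination positions; overlapping
#' hits are all reported. In `annotated` mode exactly one hit is produced per
#' supplied loop start (author numbering), whether or not it passes any rule
#' — useful for classifying known EF loops, including degenerate ones whose
#' first residue is not Asp.
#'
#' @param seqs Sequence record tibble ([sequence_record()] / [read_fasta()]).
#' @param rules Coordination rule set ([ef_rules()]).
#' @param mode `"window"` or `"annotated"`.
#' @param annotations For `annotated` mode: a tibble with columns `id` and
#'   `loop_start` (author numbering), e.g. read from a TSV.
#' @return A tibble of EF-hand hits ordered by `id`, `loop_start`:
#'   `id`, `loop_start`, `loop_sequence`, `canonical`, `failed_positions`
#'   (comma-joined labels, `""` if none) and `position_calls` (list column of
#'   per-position call tibbles).
#' @export
#' @examples
#' seqs <- sequence_record("toy", "AAADKDGDGTITTKEAAA")
#' scan_ef_hands(seqs)
scan_ef_hands <- function(seqs, rules = ef_rules(),
                          mode = c("window", "annotated"),
                          annotations = NULL) {
  mode <- match.arg(mode)
  validate_ef_rules(rules)
  if (nrow(seqs) == 0 || any(!nzchar(seqs$residues))) {
    stop_input("empty sequence input")
  }
  if (mode == "annotated" && is.null(annotations)) {
    stop_input("annotated mode needs an annotations table (id, loop_start)")
  }

  hits <- pmap(seqs, function(id, residues, numbering_offset) {
    len <- nchar(residues)
    if (mode == "window") {
      if (len < EF_LOOP_LENGTH) stop_input("sequence shorter than one EF loop (12 residues)")
      starts_idx <- seq_len(len - EF_LOOP_LENGTH + 1L)
      # pre-filter: position 1 must pass the X rule
      x_allowed <- rules$allowed[[match(1L, rules$position)]]
      if (!all(is.na(x_allowed))) {
        first_res <- substring(residues, starts_idx, starts_idx)
        starts_idx <- starts_idx[first_res %in% x_allowed]
      }
    } else {
      starts <- annotations$loop_start[annotations$id == id]
      starts_idx <- as.integer(starts) - numbering_offset + 1L
      if (any(starts_idx < 1L | starts_idx + EF_LOOP_LENGTH - 1L > len)) {
        abort(paste0("annotated loop start out of range for record '", id, "'"),
              class = "efbind_range_error")
      }
    }
    if (length(starts_idx) == 0) return(NULL)
    map(starts_idx, function(i) {
      loop_seq <- substring(residues, i, i + EF_LOOP_LENGTH - 1L)
      calls <- evaluate_loop(loop_seq, rules)
      failed <- calls$label[!calls$pass]
      tibble(
        id = id,
        loop_start = i + numbering_offset - 1L,
        loop_sequence = loop_seq,
        canonical = length(failed) == 0,
        failed_positions = paste(failed, collapse = ","),
        position_calls = list(calls)
      )
    }) |> list_rbind()
  }) |> list_rbind()

  if (is.null(hits) || nrow(hits) == 0) {
    hits <- tibble(id = character(), loop_start = integer(),
                   loop_sequence = character(), canonical = logical(),
                   failed_positions = character(), position_calls = list())
  }
  arrange(hits, .data$id, .data$loop_start)
}

#' Summarise EF-hand hits into canonical / degenerate counts
#'
#' @param hits Hit tibble from [scan_ef_hands()].
#' @return A list of class `ef_hand_summary` with `counts` (one-row tibble:
#'   `n_hits`, `count_canonical`, `count_degenerate`) and `hits` (per-hit
#'   id, loop_start, canonical flag and failure reasons).
#' @export
classify_ef_hands <- function(hits) {
  counts <- tibble(
    n_hits = nrow(hits),
    count_canonical = sum(hits$canonical),
    count_degenerate = sum(!hits$canonical)
  )
  by_hit <- hits |>
    mutate(reason = ifelse(.data$canonical, "canonical",
                           paste0("fails ", .data$failed_positions))) |>
    select("id", "loop_start", "loop_sequence", "canonical", "reason")
  structure(list(counts = counts, hits = by_hit), class = "ef_hand_summary")
}

#' @export
print.ef_hand_summary <- function(x, ...) {
  cat(sprintf("EF-hand classification: %d hits, %d canonical, %d degenerate\n",
              x$counts$n_hits, x$counts$count_canonical,
              x$counts$count_degenerate))
  print(x$hits, ...)
  invisible(x)
}

#' Write an EF-hand scan report as TSV and/or JSON
#'
#' @param hits Hit tibble from [scan_ef_hands()].
#' @param tsv,json Optional output paths; omit either.
#' @return The hit table (without the list column) invisibly.
#' @export
write_scan_report <- function(hits, tsv = NULL, json = NULL) {
  flat <- select(hits, "id", "loop_start", "loop_sequence", "canonical",
                 "failed_positions")
  if (!is.null(tsv)) readr::write_tsv(flat, tsv)
  if (!is.null(json)) {
    jsonlite::write_json(flat, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(flat)
}
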