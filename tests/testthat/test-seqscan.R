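# EF-hand loop detection and classification.

test_that("the EF1-type loop with documented coordinating residues is canonical", {
  demo <- camd_demo_sequence()
  hits <- scan_ef_hands(demo$seqs, mode = "annotated",
                        annotations = demo$annotations)
  ef1 <- hits[hits$loop_start == 759, ]
  expect_true(ef1$canonical)
  expect_identical(ef1$failed_positions, "")
  calls <- ef1$position_calls[[1]]
  # documented coordination: D at X, D at Y, S at Z, backbone T at -Y,
  # water-bridging G at -X, bidentate E at -Z
  expect_identical(calls$residue, c("D", "D", "S", "T", "G", "E"))
  expect_true(all(calls$pass))
})

test_that("the four-loop CaMD-like construct has exactly one canonical hand", {
  demo <- camd_demo_sequence()
  hits <- scan_ef_hands(demo$seqs, mode = "annotated",
                        annotations = demo$annotations)
  expect_equal(nrow(hits), 4)
  cls <- classify_ef_hands(hits)
  expect_equal(cls$counts$count_canonical, 1)
  expect_equal(cls$counts$count_degenerate, 3)
  ef2 <- hits[hits$loop_start == 800, ]
  expect_true(grepl("Z", ef2$failed_positions))
  expect_true(grepl("-Z", ef2$failed_positions))
  # window mode also finds the canonical loop, at the annotated start
  win <- scan_ef_hands(demo$seqs, mode = "window")
  expect_equal(win$loop_start[win$canonical], 759L)
})

test_that("poly-alanine fails at least X and -Z; empty hit lists count zero", {
  hits <- scan_ef_hands(sequence_record("polyA", "AAAAAAAAAAAA"),
                        mode = "annotated",
                        annotations = tibble::tibble(id = "polyA",
                                                     loop_start = 1L))
  expect_false(hits$canonical)
  failed <- strsplit(hits$failed_positions, ",")[[1]]
  expect_true(all(c("X", "-Z") %in% failed))
  empty <- classify_ef_hands(hits[0, ])
  expect_equal(empty$counts$count_canonical, 0)
})

test_that("generated fixtures classify exactly as constructed", {
  seqs <- gen_ef_sequences(canonical = 4, degenerate = 6, seed = 21)
  truth <- attr(seqs, "truth")
  hits <- scan_ef_hands(seqs, mode = "window")
  cls <- classify_ef_hands(hits)
  expect_equal(cls$counts$count_canonical, 4)
  # a loop broken only at -Z reports exactly that failure
  seqs2 <- gen_ef_sequences(canonical = 0, degenerate = 2,
                            break_positions = list("-Z"), seed = 22)
  truth2 <- attr(seqs2, "truth")
  hits2 <- scan_ef_hands(seqs2, mode = "annotated",
                         annotations = tibble::tibble(
                           id = truth2$id, loop_start = truth2$loop_start))
  expect_identical(hits2$failed_positions, c("-Z", "-Z"))
})

test_that("window mode equals a brute-force position-by-position oracle", {
  rules <- ef_rules()
  for (seed in 1:8) {
    seq_str <- withr::with_seed(seed, paste(
      sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "D", "E"),
             withr::with_seed(seed * 7, sample(20:60, 1)), replace = TRUE),
      collapse = ""))
    hits <- scan_ef_hands(sequence_record("r", seq_str), rules, "window")
    oracle <- brute_force_scan(seq_str, rules)
    if (is.null(oracle)) {
      expect_equal(nrow(hits), 0)
    } else {
      expect_equal(hits$loop_start, oracle$loop_start)
      expect_equal(hits$canonical, oracle$canonical)
      expect_equal(hits$failed_positions, oracle$failed)
    }
  }
})

test_that("scan is deterministic and monotone under rule tightening", {
  seqs <- gen_ef_sequences(canonical = 3, degenerate = 3, seed = 30)
  h1 <- scan_ef_hands(seqs, mode = "window")
  h2 <- scan_ef_hands(seqs, mode = "window")
  expect_identical(h1, h2)
  base_count <- classify_ef_hands(h1)$counts$count_canonical
  rules <- ef_rules()
  for (i in which(!purrr::map_lgl(rules$allowed, \(a) all(is.na(a))))) {
    tightened <- rules
    if (length(tightened$allowed[[i]]) > 1) {
      tightened$allowed[[i]] <- tightened$allowed[[i]][-1]
      cnt <- classify_ef_hands(
        scan_ef_hands(seqs, tightened, "window"))$counts$count_canonical
      expect_lte(cnt, base_count)
    }
  }
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(sequence_record("bad", "ABZ"), "non-standard")
  expect_error(scan_ef_hands(sequence_record("s", "ACDEFGHIKLMNP"),
                             mode = "annotated",
                             annotations = tibble::tibble(id = "s",
                                                          loop_start = 5L)),
               class = "efbind_range_error")
  expect_error(scan_ef_hands(sequence_record("s", "ACD"), mode = "window"),
               "shorter")
  bad_rules <- ef_rules()
  bad_rules$allowed[[match(12L, bad_rules$position)]] <- c("E", "D", "Q")
  expect_error(efbind:::validate_ef_rules(bad_rules), "bidentate")
})

test_that("rule sets round-trip through the YAML config", {
  rules <- ef_rules(strict_backbone = TRUE)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ef_rules(rules, path)
  back <- read_ef_rules(path)
  expect_equal(back$position, rules$position)
  expect_equal(back$allowed, rules$allowed)
  # scan results identical under the round-tripped rules
  demo <- camd_demo_sequence()
  expect_identical(
    scan_ef_hands(demo$seqs, rules, "window"),
    scan_ef_hands(demo$seqs, back, "window"))
})

test_that("FASTA and report output round-trip", {
  seqs <- gen_ef_sequences(canonical = 2, degenerate = 1, seed = 40)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  back <- read_fasta(fa)
  expect_equal(back$residues, seqs$residues)
  hits <- scan_ef_hands(back, mode = "window")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_scan_report(hits, tsv = tsv, json = jsn)
  re <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(re$loop_start, hits$loop_start)
  expect_equal(re$canonical, hits$canonical)
})
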