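# Coordination-position rule sets for the canonical EF-hand loop.
#
# The 12-residue EF loop chelates Ca2+ in a pentagonal bipyramid through six
# coordination positions, conventionally labelled X(1), Y(3), Z(5), -Y(7),
# -X(9) and -Z(12). Position 7 coordinates through its backbone carbonyl, so
# its sequence identity is unconstrained by default; position 9 coordinates
# through a bridging water hydrogen-bonded to the side chain and is
# permissive; position 12 is the invariant bidentate Glu/Asp.

EF_LOOP_LENGTH <- 12L

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Canonical EF-hand coordination rules
#'
#' Builds the per-position allowed-residue sets used to call a 12-residue
#' loop canonical. The defaults encode the common sequence preferences of
#' functional EF loops: Asp at X(1); Asp/Asn/Ser at Y(3); Asp/Asn/Ser/Thr at
#' Z(5); any residue at -Y(7) (main-chain carbonyl coordination); a
#' permissive small/polar set at -X(9) (water-mediated); and the invariant
#' bidentate Glu/Asp at -Z(12). An `NA` allowed set means the position is
#' sequence-permissive.
#'
#' @param strict_backbone If `TRUE`, position 7 (-Y) additionally requires a
#'   small residue (`G A S T C K I Q`) instead of being fully permissive.
#' @return A tibble of class `ef_rules` with columns `label`, `position`,
#'   `allowed` (list column; `NA` = permissive) and `coordination`.
#' @seealso [read_ef_rules()] to load a rule set from a YAML config.
#' @export
#' @examples
#' ef_rules()
ef_rules <- function(strict_backbone = FALSE) {
  pos7 <- if (strict_backbone) c("G", "A", "S", "T", "C", "K", "I", "Q") else NA
  rules <- tibble(
    label = c("X", "Y", "Z", "-Y", "-X", "-Z"),
    position = c(1L, 3L, 5L, 7L, 9L, 12L),
    allowed = list(
      "D",
      c("D", "N", "S"),
      c("D", "N", "S", "T"),
      pos7,
      c("S", "T", "D", "N", "E", "G", "Q"),
      c("E", "D")
    ),
    coordination = c("side chain", "side chain", "side chain",
                     "backbone carbonyl", "water-mediated",
                     "bidentate side chain")
  )
  new_ef_rules(rules)
}

new_ef_rules <- function(rules) {
  validate_ef_rules(rules)
  class(rules) <- c("ef_rules", class(tibble()))
  rules
}

validate_ef_rules <- function(rules) {
  if (!all(c("label", "position", "allowed") %in% names(rules))) {
    stop_input("rule set needs columns label, position, allowed")
  }
  if (any(rules$position < 1L | rules$position > EF_LOOP_LENGTH)) {
    stop_input("rule positions must lie in 1..12")
  }
  if (anyDuplicated(rules$position)) stop_input("duplicated rule positions")
  mz <- rules$allowed[[match(12L, rules$position)]]
  if (is.null(mz) || (!all(is.na(mz)) && !all(mz %in% c("E", "D")))) {
    stop_input("position 12 (-Z) must be a subset of {E, D}: the invariant bidentate ligand")
  }
  invisible(rules)
}

#' Read / write an EF-hand rule set as a plain-text YAML config
#'
#' The config lists, per coordination label, the loop position and the
#' allowed one-letter residues (`~`/empty for a sequence-permissive
#' position). This makes the rule set user-overridable without touching code.
#'
#' @param path File path of the YAML rule config.
#' @return `read_ef_rules()` returns an `ef_rules` tibble;
#'   `write_ef_rules()` returns `path` invisibly.
#' @export
read_ef_rules <- function(path) {
  y <- yaml::read_yaml(path)
  rules <- tibble(
    label = names(y$positions),
    position = unname(map_dbl(y$positions, "position")) |> as.integer(),
    allowed = unname(map(y$positions, function(p) {
      a <- p$allowed
      if (is.null(a) || length(a) == 0) NA else toupper(as.character(a))
    })),
    coordination = unname(map_chr(y$positions,
                                  function(p) p$coordination %||% ""))
  )
  new_ef_rules(rules)
}

#' @rdname read_ef_rules
#' @param rules An `ef_rules` tibble.
#' @export
write_ef_rules <- function(rules, path) {
  validate_ef_rules(rules)
  y <- list(
    loop_length = EF_LOOP_LENGTH,
    positions = setNames(
      pmap(list(rules$position, rules$allowed, rules$coordination),
           function(pos, allowed, coord) {
             list(position = pos,
                  allowed = if (all(is.na(allowed))) NULL else as.list(allowed),
                  coordination = coord)
           }),
      rules$label
    )
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
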