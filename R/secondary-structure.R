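#' Collapse DSSP 8-state secondary structure to 3 states
#'
#' Maps the DSSP alphabet to the conventional three classes: `H`, `G`, `I`
#' (alpha-, 3_10- and pi-helix) become helix; `E`, `B` (extended strand,
#' isolated beta-bridge) become strand; all remaining states (`T`, `S`, `C`)
#' become loop. The compact output alphabet is `H` (helix), `E` (strand),
#' `C` (loop/coil), the usual Q3 convention.
#'
#' @param ss8 Character vector of 8-state strings over `H G I E B T S C`.
#' @return Character vector of equal-length 3-state strings over `H E C`.
#' @examples
#' collapse_ss8_to_ss3("HGIEB") # "HHHEE"
#' @export
collapse_ss8_to_ss3 <- function(ss8) {
  map <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
           T = "C", S = "C", C = "C")
  vapply(ss8, function(s) {
    if (is.na(s)) return(NA_character_)
    if (nchar(s) == 0L) return("")
    ch <- strsplit(toupper(s), "")[[1]]
    out <- map[ch]
    if (anyNA(out)) {
      bad <- which(is.na(out))[1]
      stop("unknown secondary-structure state '", ch[bad],
           "' at residue ", bad, call. = FALSE)
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Per-residue 3-state names for an 8-state string
#'
#' @param ss8 A single 8-state string.
#' @return Character vector of `"helix"`, `"strand"`, `"loop"`, one per
#'   residue.
#' @examples
#' ss3_states("TSC") # loop loop loop
#' @export
ss3_states <- function(ss8) {
  s3 <- collapse_ss8_to_ss3(ss8)
  if (nchar(s3) == 0L) return(character(0))
  c(H = "helix", E = "strand", C = "loop")[strsplit(s3, "")[[1]]] |>
    unname()
}

#' Read protein secondary-structure profiles
#'
#' Two-column whitespace/tab separated text: protein id, 8-state string.
#'
#' @param path Path to the profile file.
#' @return Tibble with `protein_id`, `ss8`, `ss3` (compact `H/E/C`) and
#'   `length` columns.
#' @export
read_ss_profiles <- function(path) {
  x <- readr::read_tsv(path, col_names = c("protein_id", "ss8"),
                       col_types = "cc", comment = "#", progress = FALSE)
  x$ss8[is.na(x$ss8)] <- ""
  dplyr::mutate(x, ss3 = collapse_ss8_to_ss3(ss8), length = nchar(ss8))
}

#' Secondary-structure states at the residues affected by indels
#'
#' Looks up the 3-state structure at every residue of each affected-residue
#' span (see [affected_residues()]).
#'
#' @param spans Tibble with `indel_id`, `protein_id`, `start_residue`,
#'   `end_residue` (1-based inclusive).
#' @param profiles Tibble from [read_ss_profiles()].
#' @return Tibble with one row per (indel, residue): `indel_id`,
#'   `protein_id`, `residue`, `state`.
#' @export
ss_states_for_indels <- function(spans, profiles) {
  sp <- dplyr::left_join(spans, profiles[, c("protein_id", "ss3", "length")],
                         by = "protein_id")
  if (anyNA(sp$ss3)) {
    miss <- unique(sp$protein_id[is.na(sp$ss3)])
    stop("no secondary-structure profile for protein(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  over <- sp$end_residue > sp$length
  if (any(over)) {
    stop("residue span exceeds profile length for protein(s): ",
         paste(unique(sp$protein_id[over]), collapse = ", "), call. = FALSE)
  }
  long <- c(H = "helix", E = "strand", C = "loop")
  purrr::pmap_dfr(
    sp[, c("indel_id", "protein_id", "start_residue", "end_residue", "ss3")],
    function(indel_id, protein_id, start_residue, end_residue, ss3) {
      res <- seq.int(start_residue, end_residue)
      tibble(
        indel_id = indel_id, protein_id = protein_id, residue = res,
        state = unname(long[strsplit(substr(ss3, start_residue, end_residue),
                                     "")[[1]]])
      )
    }
  )
}

#' Cohort-level distribution of secondary-structure states
#'
#' Aggregates per-residue states into the three-state distribution, either
#' counting every affected residue (`per_residue`, the default) or one
#' majority state per indel (`per_indel`; ties broken helix > strand > loop).
#'
#' @param states Tibble from [ss_states_for_indels()].
#' @param mode `"per_residue"` or `"per_indel"`.
#' @return Tibble `state`, `n`, `pct` (class `ss_dist`).
#' @export
ss_state_distribution <- function(states, mode = c("per_residue", "per_indel")) {
  mode <- match.arg(mode)
  lev <- c("helix", "strand", "loop")
  if (mode == "per_indel") {
    states <- states |>
      dplyr::count(indel_id, state) |>
      dplyr::mutate(state = factor(state, levels = lev)) |>
      dplyr::group_by(indel_id) |>
      dplyr::arrange(dplyr::desc(n), state, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::mutate(state = as.character(state))
  }
  out <- states |>
    dplyr::count(state = factor(state, levels = lev), .drop = FALSE) |>
    dplyr::mutate(state = as.character(state),
                  pct = pct(n, sum(n)))
  class(out) <- c("ss_dist", class(out))
  out
}
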