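#' Side-chain and terminal pKa table for protein net-charge calculation
#'
#' Returns the table of ionisable groups used by [net_protein_charge()]:
#' one row per side chain (Arg, Lys, His, Asp, Glu, Cys, Tyr) plus the
#' alpha-amino and alpha-carboxyl termini, with the acid dissociation
#' constant (as pKa) and the sign of the charge the group carries when
#' ionised (+1 for bases, -1 for acids).
#'
#' The defaults are a fixed, widely used set of model-compound pKa values.
#' Published tables differ by a few tenths of a unit; pass a modified
#' table to explore that sensitivity.
#'
#' @param overrides Optional named numeric vector of pKa overrides, named
#'   by group (`"R"`, `"K"`, `"H"`, `"D"`, `"E"`, `"C"`, `"Y"`,
#'   `"Nterm"`, `"Cterm"`), e.g. `c(H = 6.0)`.
#'
#' @return A tibble with columns `group`, `pka`, `sign`.
#' @examples
#' pka_table()
#' pka_table(c(H = 6.0))
#' @export
pka_table <- function(overrides = NULL) {
  tab <- tibble::tibble(
    group = c("R", "K", "H", "D", "E", "C", "Y", "Nterm", "Cterm"),
    pka   = c(12.5, 10.8, 6.5, 3.9, 4.1, 8.5, 10.1, 8.6, 3.6),
    sign  = c(1, 1, 1, -1, -1, -1, -1, 1, -1)
  )
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || !all(names(overrides) %in% tab$group)) {
      rlang::abort("pKa overrides must be named by ionizable group (R, K, H, D, E, C, Y, Nterm, Cterm).")
    }
    tab$pka[match(names(overrides), tab$group)] <- unname(overrides)
  }
  validate_pka_table(tab)
  tab
}

validate_pka_table <- function(tab) {
  stopifnot(is.data.frame(tab), all(c("group", "pka", "sign") %in% names(tab)))
  if (anyDuplicated(tab$group) > 0) {
    rlang::abort("pKa table must contain exactly one entry per ionizable group.")
  }
  if (any(tab$pka <= 0 | tab$pka >= 14)) {
    rlang::abort("All pKa values must lie in (0, 14).")
  }
  if (!all(tab$sign %in% c(-1, 1))) {
    rlang::abort("Group signs must be +1 (base) or -1 (acid).")
  }
  invisible(tab)
}
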