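#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch net charge: the sum over basic groups of
#' \eqn{1/(1+10^{pH-pKa})} minus the sum over acidic groups of
#' \eqn{1/(1+10^{pKa-pH})}, including both chain termini. Deterministic
#' for a fixed pKa table.
#'
#' @param protein A [protein_spec()] or a one-letter sequence string.
#' @param pH Solution pH, in (0, 14).
#' @param pka A [pka_table()].
#' @param mask_cys If `TRUE`, cysteines are treated as non-ionizable
#'   (e.g. spin-label-modified constructs carry no free thiol).
#'
#' @return Net charge in elementary charges (signed, fractional).
#' @examples
#' net_protein_charge("KK", pH = 7)                   # ~ +2
#' net_protein_charge(tau_protein("dtau187"), pH = 7) # ~ +10.8
#' @export
net_protein_charge <- function(protein, pH = 7, pka = pka_table(),
                               mask_cys = FALSE) {
  if (!inherits(protein, "protein_spec")) {
    protein <- protein_spec("protein", protein)
  }
  if (!is.numeric(pH) || length(pH) != 1 || pH <= 0 || pH >= 14) {
    rlang::abort("`pH` must be a single value in (0, 14).")
  }
  validate_pka_table(pka)
  aa <- strsplit(protein$sequence, "")[[1]]
  counts <- table(factor(aa, levels = .aa_alphabet))
  if (mask_cys) counts["C"] <- 0L
  q <- 0
  for (i in seq_len(nrow(pka))) {
    g <- pka$group[i]
    n_g <- if (g %in% c("Nterm", "Cterm")) 1L else as.integer(counts[g])
    if (is.na(n_g) || n_g == 0L) next
    q <- q + if (pka$sign[i] > 0) {
      n_g / (1 + 10^(pH - pka$pka[i]))
    } else {
      -n_g / (1 + 10^(pka$pka[i] - pH))
    }
  }
  q
}

#' RNA species descriptor
#'
#' Describes an RNA polyanion by its mean nucleotide residue mass and
#' charge per nucleotide, sufficient to convert a mass concentration into
#' a negative-charge concentration. The default (330 Da, 1 charge per
#' nucleotide) is a generic single-stranded RNA; `chain_mass` (Da per
#' molecule) enables molar-ratio conversions, e.g. 25 kDa for tRNA.
#'
#' @param name Identifier.
#' @param nt_mass Mean nucleotide residue mass, Da (> 0).
#' @param charges_per_nt Negative charges per nucleotide (> 0).
#' @param chain_mass Optional mean chain mass, Da per molecule.
#' @return An object of class `rna_spec`.
#' @examples
#' rna_spec("tRNA", chain_mass = 25000)
#' @export
rna_spec <- function(name = "RNA", nt_mass = 330, charges_per_nt = 1,
                     chain_mass = NULL) {
  if (!is.numeric(nt_mass) || nt_mass <= 0) {
    rlang::abort("`nt_mass` must be > 0.")
  }
  if (!is.numeric(charges_per_nt) || charges_per_nt <= 0) {
    rlang::abort("`charges_per_nt` must be > 0.")
  }
  structure(
    list(name = name, nt_mass = nt_mass, charges_per_nt = charges_per_nt,
         chain_mass = chain_mass),
    class = "rna_spec"
  )
}

#' @export
print.rna_spec <- function(x, ...) {
  cat(sprintf("<rna_spec> %s: %.0f Da/nt, %.2g charge/nt%s\n",
              x$name, x$nt_mass, x$charges_per_nt,
              if (is.null(x$chain_mass)) "" else
                sprintf(", chain %.0f Da", x$chain_mass)))
  invisible(x)
}

#' RNA negative-charge concentration from a mass concentration
#'
#' Converts a mass concentration into a molar concentration of negative
#' charge: `mass_ugml / nt_mass * 1000 * charges_per_nt` micromolar.
#' Linear in the mass concentration.
#'
#' @param rna An [rna_spec()].
#' @param mass_ugml RNA mass concentration, ug/ml (>= 0; vectorised).
#' @return Charge concentration in uM.
#' @examples
#' rna_charge_concentration(rna_spec(), 222) # ~ 672.7 uM
#' @export
rna_charge_concentration <- function(rna, mass_ugml) {
  stopifnot(inherits(rna, "rna_spec"))
  if (any(mass_ugml < 0)) rlang::abort("`mass_ugml` must be >= 0.")
  mass_ugml / rna$nt_mass * 1000 * rna$charges_per_nt
}

#' Protein:RNA charge ratio of a mixture
#'
#' Computes the ratio of protein positive-charge concentration to RNA
#' negative-charge concentration for one or more mixture compositions.
#' The protein charge concentration is the molar concentration times the
#' Henderson-Hasselbalch net charge at the given pH; the RNA charge
#' concentration follows [rna_charge_concentration()]. Near-unity charge
#' ratios mark the complex-coacervation optimum.
#'
#' @param composition Data frame with columns `protein_uM` and
#'   `rna_ugml` (one row per mixture); optional columns `pH`, `nacl_mM`,
#'   `temperature_C` are carried through (`pH` overrides the `pH`
#'   argument row-wise).
#' @param protein A [protein_spec()].
#' @param rna An [rna_spec()].
#' @param pH Default pH for rows without their own.
#' @param pka A [pka_table()].
#' @param mask_cys Passed to [net_protein_charge()].
#'
#' @return A tibble: the composition plus `protein_net_charge`,
#'   `protein_charge_uM`, `rna_charge_uM`, `charge_ratio`.
#'   A zero RNA concentration is an error (the ratio is undefined);
#'   zero protein gives ratio 0.
#' @examples
#' charge_ratio(
#'   data.frame(protein_uM = 80, rna_ugml = 222),
#'   tau_protein("dtau187"), rna_spec("tRNA")
#' )
#' @export
charge_ratio <- function(composition, protein, rna = rna_spec(),
                         pH = 7, pka = pka_table(), mask_cys = FALSE) {
  stopifnot(is.data.frame(composition),
            all(c("protein_uM", "rna_ugml") %in% names(composition)))
  comp <- tibble::as_tibble(composition)
  if (!"pH" %in% names(comp)) comp$pH <- pH
  if (any(comp$protein_uM < 0) || any(comp$rna_ugml < 0)) {
    rlang::abort("Concentrations must be >= 0.")
  }
  if (any(comp$rna_ugml == 0)) {
    rlang::abort("RNA mass concentration is 0: the charge ratio is undefined.")
  }
  z <- vapply(unique(comp$pH), function(p) {
    net_protein_charge(protein, pH = p, pka = pka, mask_cys = mask_cys)
  }, numeric(1))
  names(z) <- as.character(unique(comp$pH))
  comp %>%
    dplyr::mutate(
      protein_net_charge = unname(z[as.character(.data$pH)]),
      protein_charge_uM = .data$protein_uM * .data$protein_net_charge,
      rna_charge_uM = rna_charge_concentration(rna, .data$rna_ugml),
      charge_ratio = .data$protein_charge_uM / .data$rna_charge_uM
    )
}

#' Charge ratio at a fixed protein:RNA mass ratio
#'
#' The charge ratio of a mixture prepared at a given protein:RNA mass
#' ratio is independent of the total mass concentration:
#' `mass_ratio * nt_mass * Z / (M * charges_per_nt)` with net charge `Z`
#' and protein molar mass `M`.
#'
#' @param mass_ratio Protein:RNA mass ratio (e.g. 7 for 7:1).
#' @inheritParams charge_ratio
#' @return The dimensionless charge ratio.
#' @examples
#' charge_ratio_from_mass_ratio(7, tau_protein("dtau187")) # ~ 1.27
#' @export
charge_ratio_from_mass_ratio <- function(mass_ratio, protein,
                                         rna = rna_spec(), pH = 7,
                                         pka = pka_table(),
                                         mask_cys = FALSE) {
  stopifnot(is.numeric(mass_ratio), all(mass_ratio > 0))
  rna_ugml <- 100
  protein_uM <- mass_ratio * rna_ugml * 1000 / protein$mass
  charge_ratio(
    tibble::tibble(protein_uM = protein_uM, rna_ugml = rna_ugml),
    protein, rna, pH = pH, pka = pka, mask_cys = mask_cys
  )$charge_ratio
}

#' Map charge ratios over a composition grid and locate the optimum
#'
#' Evaluates [charge_ratio()] on every row of a composition grid and
#' flags the predicted coacervation optimum: the composition whose
#' charge ratio is closest to 1:1 on a log scale (minimal
#' `|log(charge_ratio)|`), ties broken toward the lower total mass
#' concentration. Rows with zero RNA are flagged (`undefined = TRUE`),
#' not fatal. The optimum is invariant to grid ordering.
#'
#' @inheritParams charge_ratio
#' @return A tibble with the charge columns of [charge_ratio()] plus
#'   `total_mass_ugml`, `undefined` and `is_optimum`.
#' @examples
#' grid <- data.frame(protein_uM = c(20, 40, 80, 160), rna_ugml = 222)
#' charge_balance_map(grid, tau_protein("dtau187"))
#' @export
charge_balance_map <- function(composition, protein, rna = rna_spec(),
                               pH = 7, pka = pka_table(),
                               mask_cys = FALSE) {
  stopifnot(is.data.frame(composition), nrow(composition) > 0)
  comp <- tibble::as_tibble(composition)
  ok <- comp$rna_ugml > 0
  res_ok <- charge_ratio(comp[ok, , drop = FALSE], protein, rna,
                         pH = pH, pka = pka, mask_cys = mask_cys)
  res <- comp
  for (col in c("protein_net_charge", "protein_charge_uM",
                "rna_charge_uM", "charge_ratio")) {
    res[[col]] <- NA_real_
    res[[col]][ok] <- res_ok[[col]]
  }
  if (!"pH" %in% names(comp)) res$pH <- pH
  res$total_mass_ugml <-
    res$protein_uM * protein$mass / 1000 + res$rna_ugml
  res$undefined <- !ok
  score <- ifelse(res$undefined | res$charge_ratio <= 0, Inf,
                  abs(log(res$charge_ratio)))
  best <- which(
    score == min(score) &
      res$total_mass_ugml == min(res$total_mass_ugml[score == min(score)])
  )[1]
  res$is_optimum <- seq_len(nrow(res)) == best
  class(res) <- c("charge_map", class(res))
  res
}

#' @describeIn charge_balance_map Plot charge ratio against composition,
#'   highlighting the predicted optimum.
#' @param object A `charge_map` tibble.
#' @param ... Unused.
#' @export
autoplot.charge_map <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::filter(object, !.data$undefined),
    ggplot2::aes(x = .data$protein_uM / .data$rna_ugml,
                 y = .data$charge_ratio)
  ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_optimum), size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "protein (uM) per RNA (ug/ml)",
                  y = "protein(+):RNA(-) charge ratio",
                  colour = "optimum") +
    ggplot2::theme_minimal()
}
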