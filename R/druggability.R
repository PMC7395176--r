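# Druggability triage: Henderson-Hasselbalch protonation-state speciation
# for poly-basic compounds and Lipinski rule-of-five checks on supplied
# logP / MW / HBD / HBA.  Temperature enters only through the supplied pKa
# values (predicted at the temperature of interest upstream); no van't Hoff
# correction is applied here.

#' Protonation-state fractions of a poly-basic compound
#'
#' Closed-form Henderson-Hasselbalch speciation for a base with m
#' protonation sites described by stepwise macroscopic pKa values, ordered
#' from the most-protonated dissociation step upward (pKa1 releases the
#' first proton of the fully protonated species).  The fraction of the
#' species carrying j added protons is proportional to
#' \eqn{\prod_{k=1}^{j} 10^{pKa_{m-k+1} - pH}}, normalized over
#' j = 0..m.  The monoprotic case reduces to the familiar
#' \eqn{1 / (1 + 10^{pKa - pH})} for the neutral form.
#'
#' "Free base" is reported two ways: the fully neutral fraction (zero added
#' protons) and the fraction unprotonated at the weakest basic site, i.e.
#' the monoprotic speciation at the last (highest) pKa.  For the
#' bis-guanylhydrazones in the packaged panel (pKa 7.5 / 8.1) the
#' second reading reproduces the ~16\% free base reported at pH 7.4,
#' whereas the fully neutral diprotic fraction is ~8\%.
#'
#' @param pkas numeric vector of stepwise macroscopic basic pKa values,
#'   most-protonated step first (e.g. \code{c(7.5, 8.1)}).
#' @param ph the pH at which to speciate.
#' @return list of class \code{"ionizationResult"}: \code{ph};
#'   \code{fractions}, named numeric vector over protonation counts
#'   \code{"0"..."m"} summing to 1; \code{neutral_fraction} (zero added
#'   protons); \code{last_site_neutral_fraction} (monoprotic reading at the
#'   final pKa).
#' @examples
#' ionizationFractions(8.1, 7.4)$neutral_fraction        # 0.166
#' ionizationFractions(c(7.5, 8.1), 7.4)$neutral_fraction # ~0.081
#' @export
ionizationFractions <- function(pkas, ph) {
  if (!is.numeric(pkas) || length(pkas) == 0L || any(!is.finite(pkas)))
    stop("'pkas' must be a non-empty vector of finite pKa values")
  if (!is.numeric(ph) || length(ph) != 1L || !is.finite(ph))
    stop("'ph' must be a single finite value")
  m <- length(pkas)
  # unnormalized weight of the j-proton species relative to the free base:
  # protons add from the weakest-site step (pKa_m) downward
  logw <- c(0, cumsum(rev(pkas) - ph))   # log10 weights, j = 0..m
  logw <- logw - max(logw)               # overflow guard
  w <- 10^logw
  fractions <- w / sum(w)
  names(fractions) <- as.character(0:m)
  structure(list(
    ph = ph,
    fractions = fractions,
    neutral_fraction = fractions[["0"]],
    last_site_neutral_fraction = 1 / (1 + 10^(pkas[m] - ph))),
    class = "ionizationResult")
}

#' @export
print.ionizationResult <- function(x, ...) {
  cat("Protonation-state speciation at pH", x$ph, "\n")
  for (j in names(x$fractions))
    cat(sprintf("  +%s proton(s): %6.2f%%\n", j, 100 * x$fractions[[j]]))
  cat(sprintf("  free base (fully neutral):      %6.2f%%\n",
              100 * x$neutral_fraction))
  cat(sprintf("  free base (weakest-site, mono): %6.2f%%\n",
              100 * x$last_site_neutral_fraction))
  invisible(x)
}

#' Lipinski rule-of-five check
#'
#' Oral-bioavailability heuristics: MW <= 500 g/mol, logP <= 5, H-bond
#' donors <= 5, H-bond acceptors <= 10.  Boundary values pass.  All
#' violated rules are reported, not just the first.
#'
#' @param mw molecular weight, g/mol.
#' @param logp octanol-water partition coefficient.
#' @param hbd,hba hydrogen-bond donor and acceptor counts.
#' @return list of class \code{"lipinskiResult"}: \code{pass} (logical) and
#'   \code{violations} (character vector of failed-rule descriptions,
#'   empty on pass).
#' @examples
#' lipinskiCheck(mw = 300, logp = 2.1, hbd = 4, hba = 6)$pass
#' @export
lipinskiCheck <- function(mw, logp, hbd, hba) {
  vals <- list(mw = mw, logp = logp, hbd = hbd, hba = hba)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v) || !is.numeric(v))
      stop("missing or invalid Lipinski input: '", nm, "'")
  }
  if (mw <= 0) stop("'mw' must be positive")
  violations <- character()
  if (mw > 500)  violations <- c(violations,
                                 sprintf("MW %.1f > 500 g/mol", mw))
  if (logp > 5)  violations <- c(violations,
                                 sprintf("logP %.2f > 5", logp))
  if (hbd > 5)   violations <- c(violations,
                                 sprintf("HBD %d > 5", as.integer(hbd)))
  if (hba > 10)  violations <- c(violations,
                                 sprintf("HBA %d > 10", as.integer(hba)))
  structure(list(pass = length(violations) == 0L,
                 violations = violations),
            class = "lipinskiResult")
}

#' @export
print.lipinskiResult <- function(x, ...) {
  if (x$pass) cat("Lipinski: PASS (all four rules satisfied)\n")
  else cat("Lipinski: FAIL\n ", paste(x$violations, collapse = "\n  "),
           "\n")
  invisible(x)
}

#' Druggability table for a compound panel
#'
#' Runs speciation and the Lipinski check for each row of a compound
#' property table.
#'
#' @param compounds data.frame with columns \code{compound_id},
#'   \code{logp}, \code{mw}, \code{hbd}, \code{hba} and one or more pKa
#'   columns \code{pka1}, \code{pka2}, ... (NA for absent sites).
#' @param ph pH at which to speciate; default 7.4 (physiological).
#' @return data.frame with per-compound neutral fractions (both readings)
#'   and Lipinski outcome.
#' @export
druggabilityTable <- function(compounds, ph = 7.4) {
  need <- c("compound_id", "logp", "mw", "hbd", "hba")
  missing <- setdiff(need, names(compounds))
  if (length(missing))
    stop("compound table is missing column(s): ",
         paste(missing, collapse = ", "))
  pkaCols <- grep("^pka[0-9]+$", names(compounds), value = TRUE)
  if (!length(pkaCols)) stop("compound table has no pka columns")
  rows <- lapply(seq_len(nrow(compounds)), function(i) {
    pkas <- as.numeric(compounds[i, pkaCols])
    pkas <- pkas[is.finite(pkas)]
    ion <- ionizationFractions(pkas, ph)
    lip <- lipinskiCheck(compounds$mw[i], compounds$logp[i],
                         compounds$hbd[i], compounds$hba[i])
    data.frame(compound_id = compounds$compound_id[i],
               ph = ph,
               n_basic_sites = length(pkas),
               neutral_fraction = ion$neutral_fraction,
               last_site_neutral_fraction = ion$last_site_neutral_fraction,
               lipinski_pass = lip$pass,
               lipinski_violations = paste(lip$violations, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
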