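#' Translation initiation efficiency (TIE)
#'
#' The probability that the initiation region (codons `2..ell+1`) holds no
#' A-site, so that an initiation attempt succeeds:
#' `TIE = 1 - sum(rho[first ell codons]) = J/alpha`.  Equal to 1 when
#' ribosome traffic never obstructs initiation.
#'
#' @param densities a [density_profile()] from the exact solver or a
#'   simulation.
#' @param ell ribosome footprint in codons; defaults to the profile's.
#' @param tol tolerance for a (numerically) negative result, beyond which
#'   the profile is deemed inconsistent and an error is thrown.
#' @return Probability in `[0, 1]`.
#' @export
compute_tie <- function(densities, ell = NULL, tol = 1e-8) {
  stopifnot(inherits(densities, "density_profile"))
  if (is.null(ell)) ell <- densities$ell
  tie <- 1 - sum(densities$rho[seq_len(ell)])
  if (tie < -tol)
    stop("initiation-region densities sum to more than 1 (TIE = ",
         format(tie), "); profile inconsistent")
  max(tie, 0)
}

#' Translation elongation efficiency (TEE) per codon
#'
#' `TEE[i] = TIE/(kappa[i] * rho[i])`: the ratio of the intrinsic decoding
#' time to the total dwell time on codon `i`, equivalently the probability
#' that codons `i+1..i+ell` hold no A-site given an A-site at `i`.  A value
#' of 1 means a ribosome on codon `i` is never blocked; values below 1
#' quantify local ribosome interference.
#'
#' @param kappa a [kappa_profile()].
#' @param densities a [density_profile()] computed with the same rates.
#' @param tie the translation initiation efficiency, see [compute_tie()].
#' @return Numeric vector for codons `2..L`, clipped to `[0, 1]` (clipping
#'   recorded in attribute `clipped`); `NA` where `rho = 0` (attribute
#'   `skipped`).
#' @export
compute_tee <- function(kappa, densities, tie) {
  stopifnot(inherits(kappa, "kappa_profile"),
            inherits(densities, "density_profile"),
            length(kappa$kappa) == length(densities$rho))
  rho <- densities$rho
  tee <- ifelse(rho > 0, tie / (kappa$kappa * rho), NA_real_)
  clipped <- !is.na(tee) & (tee > 1 | tee < 0)
  tee <- pmin(pmax(tee, 0), 1)
  structure(tee, clipped = clipped, skipped = which(rho == 0) + 1L)
}

#' Per-codon time lost to ribosome collisions
#'
#' The mean extra dwell time on codon `i` due to queuing, in units of the
#' initiation time: `alpha * t_coll[i] = r[i]/TIE - 1/kappa[i]`.  Zero
#' exactly when there is no interference at codon `i`; negative values
#' (possible with noisy inputs) are returned raw with a warning since they
#' flag inconsistency.
#'
#' @param r a [normalized_profile()] or density vector for codons `2..L`.
#' @param tie translation initiation efficiency, positive.
#' @param kappa a [kappa_profile()].
#' @param warn_tol negative values below `-warn_tol` trigger the warning
#'   (default `1e-12`, so floating-point dust at the exact-zero boundary is
#'   not reported).
#' @return Numeric vector of `alpha * t_collision` per codon.
#' @export
collision_time <- function(r, tie, kappa, warn_tol = 1e-12) {
  if (inherits(r, "normalized_profile")) r <- r$r
  stopifnot(tie > 0, inherits(kappa, "kappa_profile"),
            length(r) == length(kappa$kappa))
  ct <- r / tie - 1 / kappa$kappa
  if (any(ct < -warn_tol))
    warning(sum(ct < -warn_tol), " codon(s) with negative collision time; ",
            "profile and rates are inconsistent there", call. = FALSE)
  ct
}

#' Per-gene translation-efficiency report
#'
#' Convenience assembly of the efficiency scores for one fitted gene.  TIE
#' and TEE are computed from the check-stage simulated densities (they are
#' defined through occupancy probabilities), and `mean_tee` averages only
#' codons whose fit was accepted.
#'
#' @param result an `inference_result` from [quality_check()].
#' @param r the gene's [normalized_profile()].
#' @param include_meanfield logical; include `ACCEPTED_MEANFIELD` codons in
#'   `mean_tee` (default `TRUE`).
#' @return An object of class `efficiency_report`: list with `gene_id`,
#'   `tie`, `tee` (per codon, `NA` at rejected codons), `mean_tee`,
#'   `alpha_t_coll`, `rho_over_rhomax`, and `status`.
#' @export
efficiency_report <- function(result, r, include_meanfield = TRUE) {
  stopifnot(inherits(result, "inference_result"),
            inherits(r, "normalized_profile"))
  sim <- result$sim
  prof <- sim$profile
  tie <- compute_tie(prof)
  tee <- as.numeric(compute_tee(result$kappa, prof, tie))
  accepted_lv <- if (include_meanfield)
    c("ACCEPTED_ILA", "ACCEPTED_MEANFIELD") else "ACCEPTED_ILA"
  acc <- result$status %in% accepted_lv
  tee[!(result$status %in% c("ACCEPTED_ILA", "ACCEPTED_MEANFIELD"))] <- NA
  ct <- suppressWarnings(collision_time(r, tie, result$kappa))
  structure(list(gene_id = r$gene_id, tie = tie, tee = tee,
                 mean_tee = mean(tee[acc], na.rm = TRUE),
                 alpha_t_coll = ct,
                 rho_over_rhomax = prof$rho_mean / prof$rho_max,
                 status = result$status),
            class = "efficiency_report")
}

#' Metagene elongation-efficiency profile
#'
#' Aligns genes at their START codon and summarizes the per-codon TEE
#' distribution across genes: median and quartiles at each position, over
#' the genes that have an accepted TEE there.
#'
#' @param reports list of [efficiency_report()] objects.
#' @param max_position largest codon position summarized.
#' @param include_meanfield include `ACCEPTED_MEANFIELD` codons (default
#'   `TRUE`); when `FALSE` only `ACCEPTED_ILA` codons enter.
#' @return data.frame with columns `codon`, `median`, `q1`, `q3`, `n_genes`.
#' @export
metagene_tee <- function(reports, max_position = 200L,
                         include_meanfield = TRUE) {
  stopifnot(length(reports) >= 1)
  lv <- if (include_meanfield)
    c("ACCEPTED_ILA", "ACCEPTED_MEANFIELD") else "ACCEPTED_ILA"
  pos <- seq(2L, max_position)
  out <- data.frame(codon = pos, median = NA_real_, q1 = NA_real_,
                    q3 = NA_real_, n_genes = 0L)
  for (p_i in seq_along(pos)) {
    codon <- pos[p_i]
    vals <- unlist(lapply(reports, function(rep) {
      idx <- codon - 1L
      if (idx > length(rep$tee)) return(NULL)
      if (!(rep$status[idx] %in% lv)) return(NULL)
      v <- rep$tee[idx]
      if (is.na(v)) NULL else v
    }))
    if (length(vals)) {
      qs <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
      out$q1[p_i] <- qs[1]; out$median[p_i] <- qs[2]; out$q3[p_i] <- qs[3]
      out$n_genes[p_i] <- length(vals)
    }
  }
  out
}

#' Order-of-magnitude ribosome drop-off rate
#'
#' The premature-termination probability per codon times the characteristic
#' elongation rate gives the drop-off rate whose smallness justifies
#' treating the ribosome current as conserved along the transcript:
#' about `1e-4 * 10 = 1e-3` per second, negligible against elongation.
#'
#' @param p_premature premature-termination probability per codon
#'   (default `1e-4`).
#' @param elongation_rate characteristic elongation rate in codons/s
#'   (default 10).
#' @return Drop-off rate in 1/s.
#' @export
dropoff_rate <- function(p_premature = 1e-4, elongation_rate = 10) {
  p_premature * elongation_rate
}
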