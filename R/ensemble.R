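# Ensemble statistics over docked-pose conformers: per-donor
# distance/angle ranges, Gaussian histogram fits, and a Table-2-style
# range "(mean)" report.

DONOR_LABELS <- c("Calpha_m1", "N_0", "N_p1")

#' Summarise motif-contact geometry over a conformer ensemble
#'
#' For each donor (Calpha(-1), N(0), N(+1)) the H...O distance and
#' X-H...O angle of its closest contact are collected over all models
#' where a contact exists, and summarised as min/max/mean plus a
#' least-squares Gaussian fit to the histogram density (Sturges
#' binning).  The coefficient of variation sigma/mu of the fitted
#' distribution diagnoses how tightly the binding geometry is defined
#' (~1e-2 for a well-defined site).
#'
#' @param models list of poses, each a list with `structure` and
#'   `anion`.
#' @param motif_residues three residue numbers `(i-1, i0, i+1)`.
#' @param cutoffs see [hbond_cutoffs()].
#' @param binning `"sturges"` (default) or an integer bin count.
#' @param use_density fit the density-normalised histogram (default)
#'   rather than raw counts.
#' @return a `cann_ensemble_summary` data frame: donor, metric, n, min,
#'   max, mean, fit_mu, fit_sigma, adj_r2, sigma_over_mu.  Donors (or
#'   fits) with insufficient data carry `NA` in the affected cells.
#' @export
summarize_ensemble <- function(models, motif_residues,
                               cutoffs = hbond_cutoffs(),
                               binning = "sturges", use_density = TRUE) {
  if (length(models) < 3) {
    warning("fewer than 3 models: all cells reported as insufficient data")
  }
  vals <- list()
  for (m in models) {
    mi <- map_anion_contacts(m$structure, m$anion, motif_residues,
                             cutoffs = cutoffs)
    ct <- mi$contacts
    for (d in DONOR_LABELS) {
      sub <- ct[ct$donor == d, , drop = FALSE]
      if (!nrow(sub)) next
      best <- sub[which.min(sub$d_ho), ]
      vals[[d]]$distance <- c(vals[[d]]$distance, best$d_ho)
      vals[[d]]$angle <- c(vals[[d]]$angle, best$angle_xho)
    }
  }
  out <- list()
  for (d in DONOR_LABELS) {
    for (met in c("distance", "angle")) {
      x <- vals[[d]][[met]]
      n <- length(x)
      if (n < 3 || length(models) < 3) {
        out[[length(out) + 1L]] <- data.frame(
          donor = d, metric = met, n = n, min = NA_real_, max = NA_real_,
          mean = NA_real_, fit_mu = NA_real_, fit_sigma = NA_real_,
          adj_r2 = NA_real_, sigma_over_mu = NA_real_)
        next
      }
      fit <- fit_gaussian(x, binning = binning, use_density = use_density)
      out[[length(out) + 1L]] <- data.frame(
        donor = d, metric = met, n = n, min = min(x), max = max(x),
        mean = mean(x), fit_mu = fit$mu, fit_sigma = fit$sigma,
        adj_r2 = fit$adj_r2,
        sigma_over_mu = if (is.na(fit$mu)) NA_real_ else
          fit$sigma / abs(fit$mu))
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("cann_ensemble_summary", "data.frame")
  out
}

# Least-squares Gaussian (amplitude, mu, sigma) fitted to the histogram.
# Degenerate samples (zero spread) or failed fits return NA fields.
fit_gaussian <- function(x, binning = "sturges", use_density = TRUE) {
  na <- list(mu = NA_real_, sigma = NA_real_, adj_r2 = NA_real_)
  if (length(x) < 3 || stats::sd(x) < 1e-9) return(na)
  nb <- if (identical(binning, "sturges")) grDevices::nclass.Sturges(x)
        else as.integer(binning)
  h <- graphics::hist(x, breaks = nb, plot = FALSE)
  xs <- h$mids
  ys <- if (use_density) h$density else h$counts
  nbins <- length(xs)
  if (nbins < 4) return(na)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ys ~ A * exp(-(xs - mu)^2 / (2 * sigma^2)),
      start = list(A = max(ys), mu = mean(x), sigma = stats::sd(x)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(na)
  co <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((ys - mean(ys))^2)
  if (ss_tot < 1e-12) return(na)
  r2 <- 1 - ss_res / ss_tot
  adj <- 1 - (1 - r2) * (nbins - 1) / (nbins - 3)
  list(mu = unname(co["mu"]), sigma = abs(unname(co["sigma"])), adj_r2 = adj)
}

#' @export
print.cann_ensemble_summary <- function(x, ...) {
  cat("<cann_ensemble_summary>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Render ensemble summaries as a Table-2-style report
#'
#' Each cell is formatted as "min-max (mean)".  Cells without data are
#' rendered as an em-dash placeholder; the docking binding-free-energy
#' column (not computable here) is rendered "n/a".
#'
#' @param summaries named list of `cann_ensemble_summary` objects; names
#'   are "peptide/conformation/anion" keys (e.g.
#'   `"CPS224Ac/native/sulfate"`).
#' @param path optional output file.
#' @param format `"markdown"` or `"tsv"`.
#' @return character vector of report lines, invisibly if `path` given.
#' @export
render_table2 <- function(summaries, path = NULL,
                          format = c("markdown", "tsv")) {
  format <- match.arg(format)
  if (!length(summaries)) stop("no summaries to render")
  if (is.null(names(summaries)) || any(names(summaries) == "")) {
    stop("summaries must be a named list keyed peptide/conformation/anion")
  }
  cell <- function(s, donor, metric) {
    row <- s[s$donor == donor & s$metric == metric, ]
    if (!nrow(row) || is.na(row$min)) return("-")
    sprintf("%.2f-%.2f (%.2f)", row$min, row$max, row$mean)
  }
  keys <- do.call(rbind, strsplit(names(summaries), "/"))
  if (ncol(keys) != 3) stop("keys must be peptide/conformation/anion")
  header <- c("peptide", "conformation", "anion",
              paste0("dist_", DONOR_LABELS), paste0("angle_", DONOR_LABELS),
              "binding_energy")
  rows <- lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    c(keys[i, ],
      vapply(DONOR_LABELS, function(d) cell(s, d, "distance"), ""),
      vapply(DONOR_LABELS, function(d) cell(s, d, "angle"), ""),
      "n/a")
  })
  if (format == "tsv") {
    lines <- c(paste(header, collapse = "\t"),
               vapply(rows, paste, "", collapse = "\t"))
  } else {
    lines <- c(paste0("| ", paste(header, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(header)), collapse = "|"),
                      "|"),
               vapply(rows, function(r)
                 paste0("| ", paste(r, collapse = " | "), " |"), ""))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Export per-model contact values as CSV (for re-plotting histograms)
#'
#' @param models list of poses (as for [summarize_ensemble()]).
#' @param motif_residues three residue numbers.
#' @param path output CSV path.
#' @param cutoffs see [hbond_cutoffs()].
#' @return `path`, invisibly.
#' @export
ensemble_values_csv <- function(models, motif_residues, path,
                                cutoffs = hbond_cutoffs()) {
  tab <- do.call(rbind, lapply(seq_along(models), function(m) {
    mi <- map_anion_contacts(models[[m]]$structure, models[[m]]$anion,
                             motif_residues, cutoffs = cutoffs)
    if (!nrow(mi$contacts)) return(NULL)
    cbind(model = m, mi$contacts)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
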