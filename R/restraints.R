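# NMR-restraint translation: NOE class -> upper distance limit, and the
# Karplus relation between 3J(HN-Halpha) and phi (forward and inverse).

NOE_LIMITS <- c(weak = 4.25, medium = 3.5, strong = 3.0)

#' NOE intensity class to upper distance limit
#'
#' @param cls `"weak"`, `"medium"` or `"strong"` (vectorised).
#' @return upper distance limit(s) in angstroms: 4.25 / 3.5 / 3.0.
#' @export
noe_upper_limit <- function(cls) {
  bad <- setdiff(unique(cls), names(NOE_LIMITS))
  if (length(bad)) {
    stop("unknown NOE class: ", paste(bad, collapse = ", "),
         " (allowed: weak, medium, strong)")
  }
  unname(NOE_LIMITS[cls])
}

#' Karplus curve parameters
#'
#' `3J = A cos^2(theta) + B cos(theta) + C` with
#' `theta = |phi - offset|` taken as the circular absolute difference.
#'
#' @return list with `A` = 6.4, `B` = -1.4, `C` = 1.9 (Hz) and
#'   `offset` = 60 (degrees).
#' @export
karplus_params <- function() {
  list(A = 6.4, B = -1.4, C = 1.9, offset = 60)
}

#' Three-bond coupling constant from phi (Karplus equation)
#'
#' @param phi backbone torsion in degrees (vectorised).
#' @param params see [karplus_params()].
#' @return coupling constant(s) in Hz.
#' @export
karplus_j <- function(phi, params = karplus_params()) {
  theta <- angle_diff(phi, params$offset) * pi / 180
  params$A * cos(theta)^2 + params$B * cos(theta) + params$C
}

#' Invert the Karplus equation
#'
#' Finds all phi in `(-180, 180]` with `karplus_j(phi) = J` by solving
#' the quadratic in cos(theta) exactly (tangent solutions at the curve's
#' extremes are kept; a near-zero discriminant is treated as zero) and
#' widens each solution to a +/- `window` interval; overlapping
#' intervals are merged, including across the +/-180 wrap.
#'
#' @param J observed coupling constant in Hz.
#' @param params see [karplus_params()].
#' @param window half-width of the returned intervals in degrees
#'   (default 10, the conventional phi +/- 10 restraint).
#' @return list of numeric `c(lo, hi)` intervals (degrees; an interval
#'   crossing +180 is returned with `hi > 180`, to be read modulo 360).
#'   Empty, with a warning, when `J` is unattainable.
#' @export
karplus_invert <- function(J, params = karplus_params(), window = 10) {
  # A c^2 + B c + C = J with c = cos(theta), |c| <= 1
  disc <- params$B^2 - 4 * params$A * (params$C - J)
  if (disc < 0 && disc > -1e-9 * params$A^2) disc <- 0
  if (disc < 0) {
    warning("coupling constant ", J, " Hz is not attainable by the curve")
    return(list())
  }
  cs <- (-params$B + c(-1, 1) * sqrt(disc)) / (2 * params$A)
  cs <- unique(cs[cs >= -1 - 1e-12 & cs <= 1 + 1e-12])
  cs <- pmin(1, pmax(-1, cs))
  thetas <- acos(cs) * 180 / pi
  roots <- wrap_angle(c(params$offset + thetas, params$offset - thetas))
  roots <- sort(unique(round(roots, 6)))
  # drop near-duplicates from the wrap or tangency
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > 1e-3)
    roots <- roots[keep]
    if (length(roots) > 1 && angle_diff(roots[1], roots[length(roots)]) < 1e-3) {
      roots <- roots[-length(roots)]
    }
  }
  if (!length(roots)) {
    warning("coupling constant ", J, " Hz is not attainable by the curve")
    return(list())
  }
  iv <- lapply(roots, function(r) c(lo = r - window, hi = r + window))
  merge_circular_intervals(iv)
}

# Merge overlapping [lo, hi] intervals on the phi circle.
merge_circular_intervals <- function(iv) {
  if (length(iv) <= 1) return(iv)
  iv <- iv[order(vapply(iv, `[`, 0, 1))]
  out <- list(iv[[1]])
  for (k in 2:length(iv)) {
    last <- out[[length(out)]]
    cur <- iv[[k]]
    if (cur[1] <= last[2]) {
      out[[length(out)]] <- c(lo = unname(last[1]),
                              hi = max(unname(last[2]), unname(cur[2])))
    } else {
      out[[length(out) + 1L]] <- cur
    }
  }
  # wrap: last interval reaching past +180 may merge with the first
  if (length(out) > 1) {
    first <- out[[1]]
    last <- out[[length(out)]]
    if (last[2] - 360 >= first[1]) {
      out[[1]] <- c(lo = unname(last[1]) - 360,
                    hi = max(unname(first[2]), unname(last[2]) - 360))
      out[[length(out)]] <- NULL
    }
  }
  out
}

#' Check whether a phi value lies in any returned interval
#'
#' Convenience for restraint round-trips; handles the +/-180 wrap.
#'
#' @param phi torsion in degrees.
#' @param intervals list of `c(lo, hi)` from [karplus_invert()].
#' @return logical.
#' @export
phi_in_intervals <- function(phi, intervals) {
  any(vapply(intervals, function(iv) {
    any((phi + c(-360, 0, 360)) >= iv[1] & (phi + c(-360, 0, 360)) <= iv[2])
  }, logical(1)))
}

#' Read / write NOE restraint lists
#'
#' The TSV format has columns `residue_i`, `residue_j`, `class`; the
#' DYANA-style upper-limit export adds atom names and the translated
#' limit.
#'
#' @param path TSV path.
#' @return data frame with `residue_i`, `residue_j`, `class`,
#'   `upper_limit`.
#' @export
read_noe_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("residue_i", "residue_j", "class")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("restraint TSV missing columns: ",
                         paste(miss, collapse = ", "))
  d$upper_limit <- noe_upper_limit(d$class)
  d
}

#' @rdname read_noe_tsv
#' @param restraints data frame as returned by [read_noe_tsv()].
#' @param atom_i,atom_j atom names for the exported limits (default HN).
#' @export
write_upper_limits <- function(restraints, path,
                               atom_i = "HN", atom_j = "HN") {
  if (is.null(restraints$upper_limit)) {
    restraints$upper_limit <- noe_upper_limit(restraints$class)
  }
  lines <- sprintf("%4d %-4s %4d %-4s %6.2f",
                   restraints$residue_i, atom_i,
                   restraints$residue_j, atom_j, restraints$upper_limit)
  writeLines(lines, path)
  invisible(path)
}
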