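#' Read a gas-exchange campaign CSV
#'
#' Reads records with columns `species`, `pft`, `ipar_umol`, `t_air_c`,
#' `ca_pa`, `patm_pa`, `vpd_kpa`, `psi_pd_mpa`, `gs_obs`, `gs_basis`
#' (`"co2"` or `"h2o"`) and normalizes every unit at the boundary: PAR
#' umol -> mol, vapour pressure kPa -> mole fraction using the per-row
#' pressure, and H2O-basis conductances divided by 1.6 so the core always
#' sees the CO2 basis. Malformed rows are rejected with row-numbered
#' errors; an empty file returns an empty frame with a warning.
#'
#' @param path CSV path.
#' @return Data frame with internal-unit columns `ipar`, `t_air`, `ca`,
#'   `patm`, `d`, `psi_pd`, `gs_obs`, `species`, `pft`.
#' @export
read_gas_exchange <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "pft", "ipar_umol", "t_air_c", "ca_pa", "patm_pa",
            "vpd_kpa", "psi_pd_mpa", "gs_obs", "gs_basis")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("gas-exchange file lacks columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("empty gas-exchange file: ", path)
    return(data.frame(ipar = numeric(0), t_air = numeric(0),
                      ca = numeric(0), patm = numeric(0), d = numeric(0),
                      psi_pd = numeric(0), gs_obs = numeric(0),
                      species = character(0), pft = character(0)))
  }
  bad_basis <- !raw$gs_basis %in% c("co2", "h2o")
  if (any(bad_basis)) stop("unknown gs_basis in rows: ",
                           paste(which(bad_basis), collapse = ", "))
  num <- c("ipar_umol", "t_air_c", "ca_pa", "patm_pa", "vpd_kpa",
           "psi_pd_mpa", "gs_obs")
  for (col in num) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- !is.finite(v)
    if (any(bad)) stop("non-numeric ", col, " in rows: ",
                       paste(which(bad), collapse = ", "))
    raw[[col]] <- v
  }
  bad <- raw$ipar_umol < 0 | raw$ca_pa <= 0 | raw$patm_pa <= 0 |
    raw$vpd_kpa < 0 | raw$psi_pd_mpa > 0 | raw$gs_obs < 0
  if (any(bad)) stop("out-of-range values in rows: ",
                     paste(which(bad), collapse = ", "))
  gs <- ifelse(raw$gs_basis == "h2o", raw$gs_obs / 1.6, raw$gs_obs)
  data.frame(ipar = raw$ipar_umol * 1e-6, t_air = raw$t_air_c,
             ca = raw$ca_pa, patm = raw$patm_pa,
             d = raw$vpd_kpa * 1000 / raw$patm_pa,
             psi_pd = raw$psi_pd_mpa, gs_obs = gs,
             species = raw$species, pft = raw$pft)
}

#' Read a hydraulic trait table CSV
#'
#' Columns: `pft`, optional `species`, `psi50_mpa`, optional `shape_a`,
#' optional `psi88_mpa` (used to derive the shape when `shape_a` is
#' absent), `rpmin` and `rpmin_units` (`"per_mol"` or `"per_mmol"`).
#' Resistances on the mmol basis are multiplied by 1000 on input.
#'
#' @param path CSV path.
#' @return Data frame with `pft`, `species`, `psi50`, `shape_a`, `rp_min`
#'   (mol basis).
#' @export
read_traits <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pft", "psi50_mpa", "rpmin", "rpmin_units")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("trait file lacks columns: ",
                         paste(miss, collapse = ", "))
  bad_units <- !raw$rpmin_units %in% c("per_mol", "per_mmol")
  if (any(bad_units)) stop("unknown rpmin_units in rows: ",
                           paste(which(bad_units), collapse = ", "))
  shape <- if ("shape_a" %in% names(raw)) raw$shape_a else rep(NA_real_, nrow(raw))
  if ("psi88_mpa" %in% names(raw)) {
    derive <- is.na(shape) & !is.na(raw$psi88_mpa)
    shape[derive] <- mapply(shape_from_p50_p88, raw$psi50_mpa[derive],
                            raw$psi88_mpa[derive])
  }
  if (any(is.na(shape))) stop("rows without shape_a or psi88_mpa: ",
                              paste(which(is.na(shape)), collapse = ", "))
  rp <- ifelse(raw$rpmin_units == "per_mmol", raw$rpmin * 1000, raw$rpmin)
  if (any(raw$psi50_mpa >= 0) || any(shape <= 0) || any(rp <= 0))
    stop("invalid trait values (need psi50 < 0, shape_a > 0, rpmin > 0)")
  data.frame(pft = raw$pft,
             species = if ("species" %in% names(raw)) raw$species else NA,
             psi50 = raw$psi50_mpa, shape_a = shape, rp_min = rp)
}

#' Write stomatal solutions as a tidy CSV
#'
#' One row per solve; NA diagnostics are serialized as empty cells so that
#' a round-trip read returns identical values.
#'
#' @param solutions A `"stomatal_solution"` or list of them.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_solution_table <- function(solutions, path) {
  if (inherits(solutions, "stomatal_solution")) solutions <- list(solutions)
  rows <- lapply(solutions, function(s) {
    data.frame(scheme = s$scheme, gs = s$gs, gs_h2o = s$gs_h2o,
               a_net = s$a_net, ci = s$ci, e_trans = s$e_trans,
               psi_c = s$hydraulic$psi_c, psi_m = s$hydraulic$psi_m,
               k = s$hydraulic$K, rp = s$hydraulic$rp, xi = s$hydraulic$xi,
               beta = s$beta,
               flags = paste(s$flags, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(out)
}

#' Write a fit report
#'
#' A small CSV with the fitted parameters and statistics plus a
#' human-readable log echoing the seed and the multistart table.
#'
#' @param fit A `"fit_result"`.
#' @param path Output CSV path; the log goes to `paste0(path, ".log")`.
#' @return The report data frame, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  rep_df <- data.frame(parameter = names(fit$params),
                       value = unlist(fit$params))
  stats_df <- data.frame(parameter = c("rss", "n_obs", "k_params", "nse",
                                       "rmse", "aic", "seed"),
                         value = c(fit$rss, fit$n_obs, fit$k_params,
                                   fit$nse, fit$rmse, fit$aic, fit$seed))
  out <- rbind(rep_df, stats_df)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  log_path <- paste0(path, ".log")
  con <- file(log_path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("fit with %d parameters on %d observations (seed %d)",
                       fit$k_params, fit$n_obs, fit$seed),
               sprintf("converged: %s", fit$converged),
               "multistart initial points and their RSS:",
               utils::capture.output(print(fit$multistart))), con)
  invisible(out)
}
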