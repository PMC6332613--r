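# Total MAC computation: each inhaled agent's end-tidal concentration is
# divided by its standard 1-MAC equivalent and the ratios are summed into a
# single anesthetic-depth value per timepoint.

#' Standard 1-MAC equivalent concentrations
#'
#' End-tidal volume percentages corresponding to one minimum alveolar
#' concentration for each agent: isoflurane 1.17, desflurane 6.6,
#' sevoflurane 1.8, nitrous oxide 105. Summed MAC values at or below
#' `negligible_threshold` are treated as "no inhaled anesthetic in use"
#' rather than as measurements. MAC values are deliberately not
#' age-adjusted.
#'
#' @param isoflurane,desflurane,sevoflurane,nitrous_oxide 1-MAC equivalent
#'   end-tidal percentages.
#' @param negligible_threshold Summed MAC at or below this is clinically
#'   negligible.
#' @return An object of class `mac_equivalents`.
#' @export
mac_equivalents <- function(isoflurane = 1.17, desflurane = 6.6,
                            sevoflurane = 1.8, nitrous_oxide = 105,
                            negligible_threshold = 0.001) {
  eq <- c(ISOFLURANE = isoflurane, DESFLURANE = desflurane,
          SEVOFLURANE = sevoflurane, NITROUS_OXIDE = nitrous_oxide)
  if (any(!is.finite(eq)) || any(eq <= 0)) {
    stop_input("MAC equivalents must be positive and finite")
  }
  structure(list(equivalents = eq,
                 negligible_threshold = negligible_threshold),
            class = "mac_equivalents")
}

#' Sum inhaled agents into a total MAC value
#'
#' @param agent_values Named numeric vector of end-tidal percentages; names
#'   must be inhaled agent codes (see [tvi_variables()]). Agents not named
#'   are taken as 0.
#' @param equivalents A [mac_equivalents()] object.
#' @return List with `mac` (the summed MAC) and `negligible` (`TRUE` when
#'   the sum does not exceed the negligibility threshold).
#' @examples
#' compute_total_mac(c(SEVOFLURANE = 1.8))$mac # exactly 1
#' @export
compute_total_mac <- function(agent_values, equivalents = mac_equivalents()) {
  stopifnot(inherits(equivalents, "mac_equivalents"))
  if (length(agent_values) == 0L) {
    return(list(mac = 0, negligible = TRUE))
  }
  nm <- toupper(names(agent_values) %||% character(0))
  if (length(nm) != length(agent_values) ||
      !all(nm %in% inhaled_agents())) {
    stop_input("agent_values must be named with inhaled agent codes: ",
               paste(inhaled_agents(), collapse = ", "))
  }
  if (any(!is.finite(agent_values)) || any(agent_values < 0)) {
    stop_input("agent concentrations must be finite and non-negative")
  }
  mac <- sum(agent_values / equivalents$equivalents[nm])
  list(mac = mac, negligible = mac <= equivalents$negligible_threshold)
}

#' Collapse agent rows into a summed-MAC measurement stream
#'
#' At every (case, timepoint) where at least one inhaled agent was recorded,
#' the agents are converted to MAC fractions and summed into a single row
#' with `variable = "MAC"`. Rows whose summed MAC does not exceed the
#' negligibility threshold are flagged: anesthetic is considered not in use
#' at such timepoints and they do not become MAC measurements.
#'
#' @param measurements Measurement `data.frame`.
#' @param equivalents A [mac_equivalents()] object.
#' @return A `data.frame` with columns `case_id,t_min,variable,value,source,
#'   negligible`; one row per (case, timepoint) with any agent data.
#' @export
summed_mac_stream <- function(measurements, equivalents = mac_equivalents()) {
  stopifnot(inherits(equivalents, "mac_equivalents"))
  a <- measurements[measurements$variable %in% inhaled_agents(), , drop = FALSE]
  if (nrow(a) == 0L) {
    return(data.frame(case_id = character(0), t_min = numeric(0),
                      variable = character(0), value = numeric(0),
                      source = character(0), negligible = logical(0),
                      stringsAsFactors = FALSE))
  }
  if (any(a$value < 0)) {
    stop_input("negative inhaled agent concentration encountered")
  }
  frac <- a$value / equivalents$equivalents[a$variable]
  key <- paste0(a$case_id, "\r", format(a$t_min, digits = 15))
  mac <- rowsum(frac, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(case_id = a$case_id[first], t_min = a$t_min[first],
                    variable = "MAC",
                    value = as.vector(mac[match(key[first], rownames(mac)), ]),
                    source = NA_character_,
                    stringsAsFactors = FALSE)
  out$negligible <- out$value <= equivalents$negligible_threshold
  out <- out[order(out$case_id, out$t_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prepare the analysis stream from raw measurements
#'
#' The gatekeeping sequence applied before any statistic is computed:
#' arterial MAP takes precedence over concurrent noninvasive MAP, inhaled
#' agents are summed into total MAC per timepoint, negligible MAC timepoints
#' are set aside, and the strict artifact limits are applied to MAP, BIS,
#' and summed MAC.
#'
#' @param measurements Raw measurement `data.frame`.
#' @param limits An [artifact_limits()] object.
#' @param equivalents A [mac_equivalents()] object.
#' @return List with `stream` (retained MAP/BIS/MAC rows, sorted) and
#'   `removed` (audit rows with a `reason` column: artifact limits or
#'   `negligible_mac`).
#' @export
prepare_stream <- function(measurements, limits = artifact_limits(),
                           equivalents = mac_equivalents()) {
  m <- resolve_map_source(measurements)
  mac <- summed_mac_stream(m, equivalents)
  negligible <- mac[mac$negligible, setdiff(names(mac), "negligible"),
                    drop = FALSE]
  if (nrow(negligible) > 0L) negligible$reason <- "negligible_mac"
  mac <- mac[!mac$negligible, setdiff(names(mac), "negligible"), drop = FALSE]
  mb <- m[m$variable %in% c("MAP", "BIS"), , drop = FALSE]
  filt <- remove_artifacts(rbind(mb, mac), limits)
  stream <- filt$retained[order(filt$retained$case_id, filt$retained$t_min), ,
                          drop = FALSE]
  rownames(stream) <- NULL
  removed <- rbind(filt$removed, negligible)
  rownames(removed) <- NULL
  list(stream = stream, removed = removed)
}
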