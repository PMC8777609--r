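# Rule engine for intraoperative hemodynamic management.
#
# The proactive policy is gated by an early-warning alert (HPI > 85% by
# default) and then branches on preload responsiveness (stroke volume
# variation, SVV), arterial tone (dynamic arterial elastance, Eadyn), and
# contractility (dP/dt max) to a single treatment class. The reactive policy
# applies the same branch logic but is triggered only by established
# hypotension (MAP < 65 mmHg). The numeric branch thresholds are
# configurable conventions from standard hemodynamic practice, not
# study-fixed constants.

#' Hemodynamic state snapshot
#'
#' @param map MAP in mmHg.
#' @param hpi Early-warning alert score in percent, 0-100.
#' @param svv Stroke volume variation in percent (>= 0).
#' @param eadyn Dynamic arterial elastance (dimensionless).
#' @param dpdt_max Maximum arterial dP/dt in mmHg/s.
#' @param artifact_flag `TRUE` when the arterial signal is suspected to be
#'   artifactual; alerts are then observed, not treated.
#' @return A list of class `hemodynamic_state`.
#' @export
hemodynamic_state <- function(map, hpi = 0, svv = 10, eadyn = 1,
                              dpdt_max = 800, artifact_flag = FALSE) {
  vals <- c(map = map, hpi = hpi, svv = svv, eadyn = eadyn,
            dpdt_max = dpdt_max)
  if (any(!is.finite(vals))) {
    stop_hypoburden("hemodynamic state fields must be finite",
                    "hypoburden_format_error")
  }
  if (hpi < 0 || hpi > 100) {
    stop_hypoburden("hpi must be in [0, 100]", "hypoburden_format_error")
  }
  if (svv < 0) {
    stop_hypoburden("svv must be >= 0", "hypoburden_format_error")
  }
  structure(list(map = map, hpi = hpi, svv = svv, eadyn = eadyn,
                 dpdt_max = dpdt_max,
                 artifact_flag = isTRUE(artifact_flag)),
            class = "hemodynamic_state")
}

#' Treatment rule configuration
#'
#' Thresholds for the alert gate and the three diagnostic branches, plus the
#' MAP threshold used by the reactive policy. Defaults: alert at HPI > 85%,
#' SVV > 13% selects fluid, Eadyn < 0.8 selects vasopressor, dP/dt max
#' below 480 mmHg/s selects inotrope, otherwise observation.
#'
#' @param alert_threshold Alert gate on HPI, percent (strictly greater
#'   fires).
#' @param map_threshold Reactive hypotension threshold, mmHg (strictly
#'   below fires).
#' @param svv_fluid SVV threshold in percent (strictly greater selects
#'   fluid).
#' @param eadyn_vasopressor Eadyn threshold (strictly below selects
#'   vasopressor).
#' @param dpdt_inotrope dP/dt max threshold in mmHg/s (strictly below
#'   selects inotrope).
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(alert_threshold = 85, map_threshold = 65,
                        svv_fluid = 13, eadyn_vasopressor = 0.8,
                        dpdt_inotrope = 480) {
  for (nm in c("alert_threshold", "map_threshold", "svv_fluid",
               "eadyn_vasopressor", "dpdt_inotrope")) {
    assert_scalar_number(get(nm), nm)
  }
  structure(list(alert_threshold = alert_threshold,
                 map_threshold = map_threshold,
                 svv_fluid = svv_fluid,
                 eadyn_vasopressor = eadyn_vasopressor,
                 dpdt_inotrope = dpdt_inotrope),
            class = "rule_config")
}

#' Read or write a rule configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_rule_config` returns a [rule_config()];
#'   `write_rule_config` returns `path` invisibly.
#' @export
read_rule_config <- function(path) {
  do.call(rule_config, yaml::read_yaml(path))
}

#' @rdname read_rule_config
#' @param rules A [rule_config()].
#' @export
write_rule_config <- function(rules, path) {
  yaml::write_yaml(unclass(rules), path)
  invisible(path)
}

# Shared diagnostic branch: SVV -> fluid, Eadyn -> vasopressor,
# dP/dt -> inotrope, else observe. Mutually exclusive by construction.
branch_action <- function(state, rules) {
  if (state$svv > rules$svv_fluid) return("fluid")
  if (state$eadyn < rules$eadyn_vasopressor) return("vasopressor")
  if (state$dpdt_max < rules$dpdt_inotrope) return("inotrope")
  "observe"
}

recommendation <- function(action, trigger) {
  structure(list(action = action, trigger = trigger),
            class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("Recommendation: %s (trigger: %s)\n", x$action,
              if (is.na(x$trigger)) "none" else x$trigger))
  invisible(x)
}

#' Proactive (alert-gated) treatment policy
#'
#' Fires only when the alert score exceeds the alert threshold. An
#' artifact-flagged state yields observation regardless of the branch
#' values; otherwise the diagnostic branch selects fluid, vasopressor,
#' inotrope, or observation. Deterministic for a given state and rules.
#'
#' @param state A [hemodynamic_state()].
#' @param rules A [rule_config()].
#' @return A `recommendation` with fields `action` (`"none"`, `"observe"`,
#'   `"fluid"`, `"vasopressor"`, `"inotrope"`) and `trigger`
#'   (`"proactive_alert"` or `NA` when nothing fired).
#' @export
#' @examples
#' proactive_policy(hemodynamic_state(map = 75, hpi = 90, svv = 18))
proactive_policy <- function(state, rules = rule_config()) {
  stopifnot(inherits(state, "hemodynamic_state"),
            inherits(rules, "rule_config"))
  if (state$hpi <= rules$alert_threshold) {
    return(recommendation("none", NA_character_))
  }
  if (state$artifact_flag) {
    return(recommendation("observe", "proactive_alert"))
  }
  recommendation(branch_action(state, rules), "proactive_alert")
}

#' Reactive (standard-care) treatment policy
#'
#' Fires only on established hypotension (MAP strictly below the MAP
#' threshold), then applies the same diagnostic branch as the proactive
#' policy.
#'
#' @inheritParams proactive_policy
#' @return A `recommendation`; trigger is `"reactive_hypotension"` when
#'   fired.
#' @export
reactive_policy <- function(state, rules = rule_config()) {
  stopifnot(inherits(state, "hemodynamic_state"),
            inherits(rules, "rule_config"))
  if (state$map >= rules$map_threshold) {
    return(recommendation("none", NA_character_))
  }
  recommendation(branch_action(state, rules), "reactive_hypotension")
}
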