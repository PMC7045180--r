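#' Scenario specifications
#'
#' A scenario is a named, ordered list of primitive transformations applied to
#' a [pathway_config()].  The primitives are:
#'
#' * `set_median(target, value)` -- rescale a stage distribution to a new
#'   median (spread on the log scale unchanged); `value = 0` collapses the
#'   stage to a point mass at zero.
#' * `truncate(target, cap)` -- impose a hard upper bound on a stage delay.
#' * `zero_out(target)` -- eliminate a stage delay entirely.
#' * `set_route_share(value)` / `set_route_share(value, drop_in_hospital)` --
#'   set the emergency-call share of the referral mix (see
#'   [set_route_share()]).
#' * `set_dtn_cap(value)` -- reduce the door-to-needle distribution to a new
#'   median *and* cap it at twice that median (the package's reading of
#'   "door-to-needle reduced to X min": a target-driven hospital protocol both
#'   shifts typical performance and curbs the long tail).
#' * `set_quality(value)` -- set the diagnostic-quality probability.
#' * `set_p_contra(value)` -- set the intrinsic ineligibility probability.
#'
#' Scenario `"0"` is the empty transform list.  Composite scenarios
#' concatenate the transform lists of their components; because the built-in
#' composites touch disjoint configuration fields, their composition is
#' order-invariant.
#'
#' @param id Short label, e.g. `"1B"`, `"8C"`, `"11"`.
#' @param description Human-readable summary.
#' @param transforms List of transforms, each a `list(op =, target =, value =)`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(id, description = "", transforms = list()) {
  stopifnot(is.character(id), length(id) == 1L, is.list(transforms))
  for (tr in transforms) {
    stopifnot(is.list(tr), !is.null(tr$op))
    if (!tr$op %in% c("set_median", "truncate", "zero_out", "set_route_share",
                      "set_dtn_cap", "set_quality", "set_p_contra")) {
      stop("unknown transform op: ", tr$op)
    }
  }
  structure(list(id = id, description = description, transforms = transforms),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s: %s (%d transform%s)\n", x$id, x$description,
              length(x$transforms), if (length(x$transforms) == 1) "" else "s"))
  invisible(x)
}

#' Compose scenarios
#'
#' Concatenates the transform lists of several scenarios into one composite
#' spec; composition is associative, and order-invariant whenever the
#' components touch disjoint configuration fields (true for all built-in
#' composites).
#'
#' @param ... [scenario_spec()] objects.
#' @param id,description Label for the composite.
#' @return A [scenario_spec()].
#' @export
compose_scenarios <- function(..., id, description = "") {
  parts <- list(...)
  stopifnot(length(parts) >= 1)
  scenario_spec(id, description,
                transforms = do.call(c, lapply(parts, `[[`, "transforms")))
}

transform_targets <- c("patient_delay", "responder_response", "gp_consult",
                       "on_scene", "transport", "self_transport", "dtn")

#' Apply a scenario to a pathway configuration
#'
#' Returns a new configuration with the scenario's transforms applied in
#' order; the base configuration is not modified.
#'
#' @param base A [pathway_config()].
#' @param spec A [scenario_spec()].
#' @return A new [pathway_config()].
#' @export
apply_scenario <- function(base, spec) {
  stopifnot(inherits(base, "pathway_config"), inherits(spec, "scenario_spec"))
  cfg <- base
  for (tr in spec$transforms) {
    if (tr$op %in% c("set_median", "truncate", "zero_out", "set_dtn_cap")) {
      if (is.null(tr$target) || !tr$target %in% transform_targets) {
        stop("transform targets unknown stage: ", tr$target)
      }
    }
    cfg <- switch(tr$op,
      set_median = {
        cfg$dists[[tr$target]] <- dd_scale_median(cfg$dists[[tr$target]], tr$value)
        cfg
      },
      truncate = {
        cfg$dists[[tr$target]] <- dd_truncate(cfg$dists[[tr$target]], tr$value)
        cfg
      },
      zero_out = {
        cfg$dists[[tr$target]] <- duration_dist("point_mass", value = 0)
        cfg
      },
      set_dtn_cap = {
        d <- dd_scale_median(cfg$dists[[tr$target]], tr$value)
        cfg$dists[[tr$target]] <- if (tr$value > 0) dd_truncate(d, 2 * tr$value) else d
        cfg
      },
      set_route_share = {
        cfg$route_mix <- set_route_share(cfg$route_mix, tr$value,
                                         drop_in_hospital = isTRUE(tr$drop_in_hospital))
        cfg
      },
      set_quality = {
        cfg$diagnostic_quality <- tr$value
        cfg
      },
      set_p_contra = {
        cfg$p_contra <- tr$value
        cfg
      })
  }
  # re-validate the final configuration
  pathway_config(cfg$route_mix, cfg$dists, cfg$treatment_window,
                 cfg$arrival_window, cfg$p_contra, cfg$diagnostic_quality)
}

#' Shift the referral mix towards emergency calls
#'
#' Sets the emergency-call (`call_911`) share of the referral mix to `target`;
#' the GP and self-referral shares shrink proportionally to absorb the change
#' and the in-hospital share is held fixed (in-hospital strokes cannot choose
#' a referral mode).  With `drop_in_hospital = TRUE` the in-hospital share is
#' zeroed first, so `target = 1` yields an all-911 mix.
#'
#' @param mix Named route-mix vector (see [pathway_config()]).
#' @param target New `call_911` share, `0 <= target <= 1 -` in-hospital share.
#' @param drop_in_hospital Zero the in-hospital share before reallocating.
#' @return A route-mix vector summing to 1.
#' @export
set_route_share <- function(mix, target, drop_in_hospital = FALSE) {
  stopifnot(is.numeric(target), length(target) == 1L, target >= 0, target <= 1)
  if (drop_in_hospital) mix[["in_hospital"]] <- 0
  inh <- mix[["in_hospital"]]
  if (target + inh > 1 + 1e-12) {
    stop("target 911 share plus in-hospital share exceeds 1")
  }
  rest <- 1 - target - inh
  other <- mix[c("gp", "self_referral")]
  mix[c("gp", "self_referral")] <- if (sum(other) > 0) {
    other * rest / sum(other)
  } else {
    c(rest / 2, rest / 2)
  }
  mix[["call_911"]] <- target
  mix / sum(mix)
}

tf <- function(op, target = NULL, value = NULL, ...) {
  c(list(op = op, target = target, value = value), list(...))
}

#' Built-in scenario set
#'
#' The full published scenario grid: single-factor best-practice and optimised
#' variants plus their combinations.
#'
#' * `0` -- current practice (empty transform list).
#' * `1A/1B/1C` -- patient delay median rescaled to 30 / 15 / 0 min.
#' * `2A/2B` -- emergency-call share raised to 60% / 100% (2B also drops the
#'   in-hospital share so the mix is all-911).
#' * `3` = 1B + 2A; `4` = 1C + 2B.
#' * `5` -- first-responder response time eliminated.
#' * `6A/6B/6C` -- on-scene time capped at 15 / 10 min / eliminated.
#' * `7A` -- ambulance transport eliminated (mobile stroke unit stationed at
#'   the hospital); `7B` -- response and transport both eliminated.
#' * `8A/8B/8C` -- door-to-needle reduced to 30 / 25 / 20 min (median rescale
#'   plus a cap at twice the new median); `8D` -- eliminated.
#' * `9` = 6B + 7A + 8C; `10` = 5 + 6C + 7B + 8D.
#' * `11` = 3 + 9; `12` = 4 + 10 plus diagnostic quality set to 100% and the
#'   unobserved GP-consult / self-transport stages eliminated, so every delay
#'   in the configuration is a point mass at zero.
#'
#' @return Named list of [scenario_spec()], in published order.
#' @export
builtin_scenarios <- function() {
  s <- list()
  s[["0"]] <- scenario_spec("0", "current practice")
  s[["1A"]] <- scenario_spec("1A", "patient delay reduced to 30 min",
                             list(tf("set_median", "patient_delay", 30)))
  s[["1B"]] <- scenario_spec("1B", "patient delay reduced to 15 min",
                             list(tf("set_median", "patient_delay", 15)))
  s[["1C"]] <- scenario_spec("1C", "patient delay reduced to 0 min",
                             list(tf("set_median", "patient_delay", 0)))
  s[["2A"]] <- scenario_spec("2A", "911 referral share raised to 60%",
                             list(tf("set_route_share", value = 0.60)))
  s[["2B"]] <- scenario_spec("2B", "911 referral share raised to 100%",
                             list(tf("set_route_share", value = 1.00,
                                     drop_in_hospital = TRUE)))
  s[["3"]] <- compose_scenarios(s[["1B"]], s[["2A"]], id = "3",
                                description = "combined best-practice patient responsiveness")
  s[["4"]] <- compose_scenarios(s[["1C"]], s[["2B"]], id = "4",
                                description = "optimised patient responsiveness")
  s[["5"]] <- scenario_spec("5", "first-responder response time eliminated",
                            list(tf("zero_out", "responder_response")))
  s[["6A"]] <- scenario_spec("6A", "on-scene time capped at 15 min",
                             list(tf("truncate", "on_scene", 15)))
  s[["6B"]] <- scenario_spec("6B", "on-scene time capped at 10 min",
                             list(tf("truncate", "on_scene", 10)))
  s[["6C"]] <- scenario_spec("6C", "on-scene time eliminated",
                             list(tf("zero_out", "on_scene")))
  s[["7A"]] <- scenario_spec("7A", "ambulance transport eliminated (MSU)",
                             list(tf("zero_out", "transport")))
  s[["7B"]] <- scenario_spec("7B", "all ambulance delays eliminated",
                             list(tf("zero_out", "responder_response"),
                                  tf("zero_out", "transport")))
  s[["8A"]] <- scenario_spec("8A", "door-to-needle reduced to 30 min",
                             list(tf("set_dtn_cap", "dtn", 30)))
  s[["8B"]] <- scenario_spec("8B", "door-to-needle reduced to 25 min",
                             list(tf("set_dtn_cap", "dtn", 25)))
  s[["8C"]] <- scenario_spec("8C", "door-to-needle reduced to 20 min",
                             list(tf("set_dtn_cap", "dtn", 20)))
  s[["8D"]] <- scenario_spec("8D", "door-to-needle eliminated",
                             list(tf("zero_out", "dtn")))
  s[["9"]] <- compose_scenarios(s[["6B"]], s[["7A"]], s[["8C"]], id = "9",
                                description = "combined best-practice pathway set-up")
  s[["10"]] <- compose_scenarios(s[["5"]], s[["6C"]], s[["7B"]], s[["8D"]],
                                 id = "10",
                                 description = "optimised pathway set-up")
  s[["11"]] <- compose_scenarios(s[["3"]], s[["9"]], id = "11",
                                 description = "combined best practices, responsiveness + set-up")
  s[["12"]] <- compose_scenarios(
    s[["4"]], s[["10"]],
    scenario_spec("12x", "perfect diagnostics, unobserved stages eliminated",
                  list(tf("set_quality", value = 1),
                       tf("zero_out", "gp_consult"),
                       tf("zero_out", "self_transport"))),
    id = "12", description = "optimised responsiveness + set-up")
  s
}
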