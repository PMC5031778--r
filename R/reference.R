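#' Published logistic flight-curve parameters for codling moth
#'
#' Reference parameter set for the Pennsylvania codling moth (PCM) logistic
#' flight models and the PETE reference model: logit-scale intercept
#' (`beta0`), slope per degC-day from biofix (`beta1`), their standard
#' errors, and the adjusted R-squared of the logit-linear fit, for each
#' generation flight, lure (`CM_L2`, `CM_DAC`, or the tabulated `PETE`
#' reference), orchard type and cutoff mode. Male models are reported under
#' both the `constrained` (PETE-derived cutoffs) and `unconstrained`
#' (observed flight shut-down cutoffs) modes; the female model (CM DAC
#' lures, which attract both sexes) is reported without a cutoff-mode
#' designation and carries `model = "female"`.
#'
#' These rows parameterize the reference curves used for model comparison
#' and for the default settings of the trap-capture simulator.
#'
#' @return Tibble with columns `model`, `generation`, `lure`, `orchard`,
#'   `sex`, `beta0`, `se_beta0`, `beta1`, `se_beta1`, `adj_r2`.
#' @seealso [reference_flight_model()], [pete_flight_model()]
#' @export
cm_flight_parameters <- function() {
  male <- dplyr::tribble(
    ~model,          ~generation, ~lure,    ~orchard,     ~beta0,  ~se_beta0, ~beta1, ~se_beta1, ~adj_r2,
    "constrained",   1L,          "CM_L2",  "abandoned",  -3.912,  0.113,     0.008,  0.0003,    0.89,
    "constrained",   1L,          "CM_L2",  "commercial", -3.755,  0.129,     0.008,  0.0003,    0.87,
    "constrained",   1L,          "PETE",   NA,           -3.517,  0.133,     0.012,  0.0003,    0.98,
    "constrained",   1L,          "CM_DAC", "abandoned",  -3.987,  0.130,     0.009,  0.0003,    0.89,
    "constrained",   1L,          "CM_DAC", "commercial", -3.513,  0.125,     0.008,  0.0003,    0.88,
    "constrained",   2L,          "CM_L2",  "abandoned",  -9.507,  0.204,     0.007,  0.0002,    0.95,
    "constrained",   2L,          "CM_L2",  "commercial", -9.439,  0.471,     0.006,  0.0003,    0.81,
    "constrained",   2L,          "PETE",   NA,           -11.391, 0.199,     0.008,  0.0001,    0.99,
    "constrained",   2L,          "CM_DAC", "abandoned",  -9.756,  0.243,     0.007,  0.0002,    0.94,
    "constrained",   2L,          "CM_DAC", "commercial", -9.930,  0.416,     0.007,  0.0003,    0.84,
    "unconstrained", 1L,          "CM_L2",  "abandoned",  -3.954,  0.106,     0.008,  0.0002,    0.92,
    "unconstrained", 1L,          "CM_L2",  "commercial", -3.799,  0.121,     0.008,  0.0003,    0.90,
    "unconstrained", 1L,          "PETE",   NA,           -3.517,  0.133,     0.012,  0.0003,    0.98,
    "unconstrained", 1L,          "CM_DAC", "abandoned",  -3.978,  0.122,     0.008,  0.0003,    0.91,
    "unconstrained", 1L,          "CM_DAC", "commercial", -3.508,  0.107,     0.008,  0.0002,    0.92,
    "unconstrained", 2L,          "CM_L2",  "abandoned",  -9.303,  0.206,     0.006,  0.0001,    0.95,
    "unconstrained", 2L,          "CM_L2",  "commercial", -10.290, 0.391,     0.006,  0.0002,    0.87,
    "unconstrained", 2L,          "PETE",   NA,           -11.391, 0.199,     0.008,  0.0001,    0.99,
    "unconstrained", 2L,          "CM_DAC", "abandoned",  -9.392,  0.255,     0.006,  0.0002,    0.92,
    "unconstrained", 2L,          "CM_DAC", "commercial", -11.692, 0.459,     0.007,  0.0003,    0.87
  )
  male$sex <- "male"
  female <- dplyr::tribble(
    ~model,   ~generation, ~lure,    ~orchard,     ~beta0,  ~se_beta0, ~beta1, ~se_beta1, ~adj_r2,
    "female", 1L,          "CM_DAC", "abandoned",  -3.771,  0.192,     0.016,  0.0007,    0.95,
    "female", 1L,          "CM_DAC", "commercial", -4.129,  0.240,     0.017,  0.0009,    0.94,
    "female", 2L,          "CM_DAC", "abandoned",  -10.730, 0.836,     0.012,  0.0009,    0.85,
    "female", 2L,          "CM_DAC", "commercial", -8.188,  2.160,     0.009,  0.0002,    0.48
  )
  female$sex <- "female"
  dplyr::bind_rows(male, female)[, c("model", "generation", "lure", "orchard",
                                     "sex", "beta0", "se_beta0", "beta1",
                                     "se_beta1", "adj_r2")]
}

#' Reference flight model as a `flight_fit`
#'
#' Looks up one row of [cm_flight_parameters()] and wraps it with
#' [flight_model()] so it can be predicted from and compared directly.
#'
#' @param model Cutoff mode: `"constrained"`, `"unconstrained"`, or
#'   `"female"`.
#' @param generation Generation flight, 1 or 2.
#' @param lure `"CM_L2"`, `"CM_DAC"`, or `"PETE"` for the reference model.
#' @param orchard `"abandoned"` or `"commercial"`; ignored for the PETE rows.
#' @return A `flight_fit`.
#' @examples
#' reference_flight_model("unconstrained", 1, "CM_L2", "commercial")
#' @export
reference_flight_model <- function(model = c("unconstrained", "constrained", "female"),
                                   generation = 1, lure = "CM_L2",
                                   orchard = NULL) {
  model <- match.arg(model)
  tab <- cm_flight_parameters()
  row <- tab[tab$model == model & tab$generation == generation &
               tab$lure == lure &
               (lure == "PETE" | is.null(orchard) | tab$orchard %in% orchard), ]
  if (nrow(row) != 1) {
    abort("Reference lookup did not identify a unique parameter row; give `orchard` for PCM rows.")
  }
  flight_model(
    beta0 = row$beta0, beta1 = row$beta1,
    se_beta0 = row$se_beta0, se_beta1 = row$se_beta1, adj_r2 = row$adj_r2,
    label = paste(stats::na.omit(c(row$model, paste0("gen ", row$generation),
                            row$lure, row$orchard)), collapse = " ")
  )
}

#' @rdname reference_flight_model
#' @export
pete_flight_model <- function(generation = 1) {
  reference_flight_model("unconstrained", generation, "PETE")
}
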