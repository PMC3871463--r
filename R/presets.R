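preset_required_keys <- c("schema_version", "description", "po_law",
                          "rate_law", "perm", "N", "sigma_o_over_i")

check_keys <- function(x, required, where, optional = character(0)) {
  unknown <- setdiff(names(x), c(required, optional))
  if (length(unknown)) {
    stop(config_error(paste0(where, ".", unknown[1]), "unknown key"))
  }
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop(config_error(paste0(where, ".", missing[1]), "missing key"))
  }
  invisible(TRUE)
}

config_error <- function(field, msg) {
  structure(class = c("config_error", "error", "condition"),
            list(message = sprintf("config field '%s': %s", field, msg),
                 call = NULL, field = field))
}

#' List shipped channel-model presets
#'
#' @return Character vector of preset names usable with [load_preset()].
#' @export
list_presets <- function() {
  dir <- system.file("extdata", "presets", package = "cngrectify")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

#' Load a channel-model preset
#'
#' Presets are versioned key-value (YAML) files describing the gating,
#' kinetic and open-pore laws of a permeant-ion condition (Na-like,
#' Rb-like, Cs-like, MA-like, DMA-like, EA-like, WT-DMA, R2Q-DMA).
#' Unknown keys are rejected.
#'
#' @param name preset name (see [list_presets()]) or path to a preset
#'   YAML file.
#' @param N optional channel-count override.
#' @return A [channel_model()].
#' @export
load_preset <- function(name, N = NULL) {
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", "presets", paste0(name, ".yaml"),
                package = "cngrectify")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop(config_error("model.preset",
                      sprintf("preset '%s' not found (have: %s)", name,
                              paste(list_presets(), collapse = ", "))))
  }
  cfg <- yaml::read_yaml(path)
  model_from_config(cfg, where = "preset", N = N)
}

# Build a channel_model from a parsed preset / inline-parameter list.
model_from_config <- function(cfg, where = "model", N = NULL) {
  check_keys(cfg, setdiff(preset_required_keys, "description"), where,
             optional = "description")
  if (cfg$schema_version != 1) {
    stop(config_error(paste0(where, ".schema_version"), "unsupported version"))
  }
  check_keys(cfg$po_law, c("A", "V_mid1", "k1", "V_mid2", "k2"),
             paste0(where, ".po_law"))
  check_keys(cfg$rate_law, c("a0", "za", "b0", "zb"),
             paste0(where, ".rate_law"))
  check_keys(cfg$perm, c("g_plus", "g_minus", "V_s"), paste0(where, ".perm"))
  po <- two_boltzmann(cfg$po_law$A,
                      boltzmann_component(cfg$po_law$V_mid1, cfg$po_law$k1),
                      boltzmann_component(cfg$po_law$V_mid2, cfg$po_law$k2))
  rl <- rate_law(cfg$rate_law$a0, cfg$rate_law$za,
                 cfg$rate_law$b0, cfg$rate_law$zb)
  pm <- permeation_law(cfg$perm$g_plus, cfg$perm$g_minus, cfg$perm$V_s)
  channel_model(po, rl, pm, N = if (is.null(N)) cfg$N else N,
                sigma_o_over_i = cfg$sigma_o_over_i)
}
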