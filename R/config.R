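#' Read a parameter configuration file
#'
#' Parses a JSON configuration with the flat keys `lambda_nm`,
#' `a_um2_per_min`, `k_um_per_min_per_uM`, `cc_uM`, `ct_uM` and either
#' `V_L` or an `egg` block (`de_um`, `h_um`, `df_um`, from which the
#' ectoplasm volume is computed). Keys that are absent fall back to the
#' chosen preset. Supplying both `V_L` and `egg` is an error (the two
#' prescriptions of the volume would conflict).
#'
#' @param path Path to a JSON file, or `NULL` for preset defaults only.
#' @param preset `"generic"` or `"beroe"`; the base values that config keys
#'   override.
#' @param overrides Named list of the same keys, winning over file values
#'   (the CLI maps flags here).
#' @return A list with `params` ([tubulin_params()]) and `geometry`
#'   ([egg_geometry()] or `NULL`).
#' @export
read_config <- function(path = NULL, preset = c("generic", "beroe"),
                        overrides = list()) {
  preset <- match.arg(preset)
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e) {
                      stop("malformed config '", path, "': ",
                           conditionMessage(e), call. = FALSE)
                    })
  }
  known <- c("lambda_nm", "a_um2_per_min", "k_um_per_min_per_uM",
             "cc_uM", "ct_uM", "V_L", "egg")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; known keys: ", paste(known, collapse = ", "), call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  if (!is.null(cfg$V_L) && !is.null(cfg$egg)) {
    stop("config keys 'V_L' and 'egg' both set: the cytoplasmic volume is ",
         "doubly prescribed; keep one", call. = FALSE)
  }

  geometry <- NULL
  if (!is.null(cfg$egg)) {
    egg <- cfg$egg
    geometry <- egg_geometry(d_e = egg$de_um %||% 1000,
                             h   = egg$h_um  %||% 5,
                             d_f = egg$df_um %||% 15)
  } else if (preset == "beroe") {
    geometry <- egg_geometry()
  }

  base <- cell_preset(preset, geometry = geometry %||% egg_geometry())
  V <- if (!is.null(cfg$V_L)) {
    cfg$V_L
  } else if (!is.null(geometry)) {
    ectoplasm_volume(geometry)
  } else {
    base$V
  }
  params <- tubulin_params(
    lambda_nm = cfg$lambda_nm %||% (base$lambda_um * 1e3),
    a   = cfg$a_um2_per_min %||% base$a,
    k   = cfg$k_um_per_min_per_uM %||% base$k,
    c_c = cfg$cc_uM %||% base$c_c,
    c_t = cfg$ct_uM %||% base$c_t,
    V   = V)
  list(params = params, geometry = geometry)
}
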