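# Run configuration: YAML/JSON files with sections well / grid / ddm /
# arousal / fit. Unknown keys are rejected; missing keys take defaults.

config_defaults <- function() {
  list(
    well = list(Eb = 1, EwL = NULL, EwR = NULL, Em = NULL, w = NULL,
                e = NULL, m_gap = NULL, xbL = 0, correct_side = "right",
                E_edge = NULL),
    grid = list(n = 512L, padding = 0L),
    ddm = list(d2 = 1, z = 1, x0 = 0, lam = 1),
    arousal = list(method = "B", alpha = 1, T0 = 0.3,
                   window = list(delta = NULL, k = 11L),
                   alpha_grid = list(from = 0, to = 200, length = 50L),
                   sampler = list(family = "uniform", Emax = NULL,
                                  mean = NULL, sd = NULL)),
    fit = list(P = 3L, C = 2L, coherence = c(8, 32), m_gap = 0.6,
               particles = 60L, iters = 300L, restarts = 3L,
               grid_n = 256L, seed = 1L, bounds = NULL))
}

# recursive merge of user config into defaults; unknown keys error with
# their full dotted path
merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop(sprintf("config error: unknown key `%s`", full), call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("config error: `%s` must be a mapping", full),
             call. = FALSE)
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

check_scalar <- function(cfg, key, test, what) {
  v <- cfg
  for (k in strsplit(key, ".", fixed = TRUE)[[1]]) v <- v[[k]]
  if (!is.null(v) && !test(v))
    stop(sprintf("config error: `%s` %s", key, what), call. = FALSE)
  invisible(v)
}

validate_config <- function(cfg) {
  pos <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0
  nneg <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0
  check_scalar(cfg, "well.w", pos, "must be > 0")
  check_scalar(cfg, "well.e", nneg, "must be >= 0")
  check_scalar(cfg, "well.m_gap", nneg, "must be >= 0")
  if (!is.null(cfg$well$EwL) && cfg$well$EwL >= cfg$well$Eb)
    stop("config error: `well.EwL` must lie below Eb", call. = FALSE)
  if (!is.null(cfg$well$EwR) && cfg$well$EwR >= cfg$well$Eb)
    stop("config error: `well.EwR` must lie below Eb", call. = FALSE)
  if (!cfg$well$correct_side %in% c("left", "right"))
    stop("config error: `well.correct_side` must be left or right",
         call. = FALSE)
  check_scalar(cfg, "grid.n", function(x) pos(x) && x >= 3,
               "must be an integer >= 3")
  check_scalar(cfg, "ddm.d2", pos, "must be > 0")
  check_scalar(cfg, "ddm.z", pos, "must be > 0")
  check_scalar(cfg, "arousal.T0", nneg, "must be >= 0")
  check_scalar(cfg, "arousal.alpha", nneg, "must be >= 0")
  if (!cfg$arousal$method %in% c("A", "B"))
    stop("config error: `arousal.method` must be A or B", call. = FALSE)
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration with sections `well`, `grid`,
#' `ddm`, `arousal` and `fit`, applies defaults for missing keys, rejects
#' unknown keys, and validates values; errors name the offending key path.
#'
#' @param path Configuration file (`.yaml`/`.yml`/`.json`).
#' @return Validated configuration list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config error: no such file: ", path, call. = FALSE)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- validate_config(merge_config(config_defaults(), user))
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' @param cfg A `run_config` (or plain list with the same sections).
#' @param path Output YAML file.
#' @return Invisibly, `path`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(drop_nulls(unclass(cfg)), path)
  invisible(path)
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, drop_nulls)
  x[!vapply(x, is.null, logical(1))]
}

#' Well specification from a configuration
#'
#' @param cfg A [load_config()] result.
#' @return A [well_spec()].
#' @export
config_well_spec <- function(cfg) {
  w <- cfg$well
  for (k in c("EwL", "EwR", "Em", "w", "e", "m_gap"))
    if (is.null(w[[k]]))
      stop(sprintf("config error: `well.%s` is required", k), call. = FALSE)
  well_spec(Eb = w$Eb, EwL = w$EwL, EwR = w$EwR, Em = w$Em, w = w$w,
            e = w$e, m_gap = w$m_gap, xbL = w$xbL,
            correct_side = w$correct_side, E_edge = w$E_edge)
}

# FNV-1a 32-bit hash of the canonical config text, used to stamp output
# files. The 32-bit product is formed in two 16-bit halves so it stays
# exact in double precision.
fnv1a32 <- function(text) {
  bytes <- utf8ToInt(enc2utf8(text))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_u32(h, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

bitwXor_u32 <- function(a, b) {
  # xor on [0, 2^32) via two 16-bit halves (R's bitwXor is 32-bit signed)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor((a %/% 65536) %% 65536, (b %/% 65536) %% 65536)
  hi * 65536 + lo
}

#' Configuration hash
#'
#' Short stable FNV-1a hash of the canonical (YAML) form of a
#' configuration, embedded in output-file headers for provenance.
#'
#' @param cfg A configuration list.
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  fnv1a32(yaml::as.yaml(drop_nulls(unclass(cfg))))
}

output_header <- function(cfg = NULL, seed = NULL) {
  parts <- c(sprintf("wellddm %s",
                     as.character(utils::packageVersion("wellddm"))))
  if (!is.null(cfg)) parts <- c(parts, sprintf("config=%s", config_hash(cfg)))
  if (!is.null(seed)) parts <- c(parts, sprintf("seed=%s", seed))
  paste(parts, collapse = " ")
}
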