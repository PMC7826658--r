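# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards so that
#' generators never leak RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' @noRd
is_binary_mask <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
}

#' @noRd
as_mask <- function(m) {
  if (is.logical(m)) m else matrix(as.logical(m), nrow(m), ncol(m))
}

#' @noRd
stop_perfmap <- function(class, msg, ...) {
  stop(structure(class = c(class, "perfmap_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# FNV-1a over the serialized object; provenance fingerprint for reports.
#' @noRd
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2L)
  h <- 2166136261
  for (b in as.integer(raw)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619, in doubles:
    # split h to keep every intermediate below 2^53
    h <- (16777619 * (h %% 65536) + ((16777619 * (h %/% 65536)) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
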