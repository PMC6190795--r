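#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition so callers/tests can distinguish error kinds.
#' @noRd
stop_cefapop <- function(class, ...) {
  msg <- paste0(...)
  stop(structure(
    class = c(class, "cefapop_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' FNV-1a hash of a character scalar, returned as 8 hex digits.
#' Used to stamp output tables with a configuration fingerprint.
#' @noRd
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    # 32-bit modular multiply by the FNV prime 16777619, in double arithmetic
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Deterministically derive stage seeds from one master seed.
#' Keeps every derived seed strictly below 2^31.
#' @noRd
derive_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Round to a number of significant figures with round-half-even,
#' matching the convention used in reported threshold/percentage tables.
#' @noRd
signif_even <- function(x, digits = 3) {
  out <- x
  nz <- is.finite(x) & x != 0
  if (any(nz)) {
    mag <- floor(log10(abs(x[nz])))
    scale <- 10^(digits - 1 - mag)
    out[nz] <- round(x[nz] * scale) / scale
  }
  out
}

#' Write a delimited table with provenance header comments.
#' @noRd
write_stamped_table <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  stamp <- sprintf(
    "# cefapop table | seed: %s | config_hash: %s",
    if (is.null(seed)) "NA" else seed,
    if (is.null(config_hash)) "NA" else config_hash
  )
  writeLines(stamp, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
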