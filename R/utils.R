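# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
}

.is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min && x == floor(x)
}

.is_prob <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

#' Derive a child seed from a master seed and a stage label
#'
#' Deterministic scheme used by the pipeline so that every random stage
#' (fixture generation, per-animal cell sampling, count noise, digestion)
#' gets its own reproducible seed: a rolling polynomial hash of the stage
#' name is combined with the master seed and a replicate index modulo a
#' 31-bit prime. Changing any of the three inputs changes the child seed.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. `"fixture"`, `"rnaseq"`).
#' @param index non-negative integer replicate index within the stage.
#' @return a positive integer seed strictly below 2^31.
#' @export
stage_seed <- function(master, stage, index = 0L) {
  .assert(length(master) == 1 && is.finite(master), "master seed must be a single number")
  .assert(is.character(stage) && length(stage) == 1, "stage must be a single string")
  codes <- utf8ToInt(stage)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 1000003
  s <- (abs(master) %% 2147483629) * 1000003 + h * 8191 + index * 127 + 17
  s <- s %% 2147483629
  if (s == 0) s <- 1
  as.integer(s)
}

# Geometric mean of strictly positive values.
.geo_mean <- function(x) exp(mean(log(x)))

# Write a data.frame as TSV with '# key: value' provenance comment lines.
.write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(provenance)) {
    for (k in names(provenance)) {
      writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
    }
  }
  # full-precision doubles so files round-trip losslessly
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.double(df2[[j]])) df2[[j]] <- sprintf("%.17g", df2[[j]])
  }
  utils::write.table(df2, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Short stable hash of an arbitrary config-like list, for provenance headers.
.config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  codes <- utf8ToInt(s)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 68719476731  # 2^36-ish prime
  paste0(format(as.hexmode(h %/% 65536), width = 6),
         format(as.hexmode(h %% 65536), width = 4))
}

.canon_condition <- function(x) {
  x <- gsub("−", "-", x)  # typographic minus -> ASCII
  .assert(all(x %in% c("Cre+", "Cre-")),
          "condition labels must be 'Cre+' or 'Cre-' (got: %s)",
          paste(unique(setdiff(x, c("Cre+", "Cre-"))), collapse = ", "))
  x
}
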