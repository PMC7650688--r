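# internal helpers shared across modules

.hap_env <- new.env(parent = emptyenv())

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so reproducible simulations never disturb the surrounding
#' random stream.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip the version suffix from a RefSeq accession ("NM_000352.4" -> "NM_000352")
accession_base <- function(x) sub("\\.\\d+$", "", x)

read_tsv_strict <- function(path, required = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  # read as character, then promote purely numeric columns; this keeps
  # single-letter alleles ("T") from collapsing into logicals
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "",
                          colClasses = "character", ...)
  for (j in seq_along(df)) {
    x <- df[[j]]
    nonempty <- x[!is.na(x) & nzchar(x)]
    if (length(nonempty) &&
        all(grepl("^-?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$",
                  nonempty))) {
      df[[j]] <- as.numeric(x)
      if (all(df[[j]] == round(df[[j]]), na.rm = TRUE) &&
          all(abs(df[[j]]) < .Machine$integer.max, na.rm = TRUE) &&
          !any(grepl("[eE.]", nonempty))) {
        df[[j]] <- as.integer(df[[j]])
      }
    } else {
      df[[j]][!is.na(x) & !nzchar(x)] <- NA_character_
    }
  }
  if (!is.null(required) && !all(required %in% names(df))) {
    stop("snapshot schema mismatch in ", basename(path), ": missing column(s) ",
         paste(setdiff(required, names(df)), collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
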