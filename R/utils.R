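#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cmdscale cutree var dbinom dnbinom dpois hclust as.dist mad
#'   median optimize p.adjust pchisq phyper pnorm pt quantile rbinom rlnorm
#'   rnbinom rnorm rpois runif sd t.test glm.fit poisson complete.cases
#'   setNames coef
#' @importFrom utils read.delim write.table head combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators are pure in (cfg, seed).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-stage seed derived from a single global seed, kept
# within 32-bit integer range.
derive_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 101L, profile = 211L, de_serum = 307L, de_tissue = 401L,
    coexpress = 503L, overtarget = 601L, enrich = 701L, relquant = 809L
  )
  off <- offsets[[stage]] %||% 997L
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

#' Write a table as TSV with an optional comment header
#'
#' All pipeline outputs are tab-separated with `#`-prefixed header lines
#' carrying provenance (e.g. a config hash), which downstream readers skip.
#'
#' @param x data frame to write.
#' @param path output file path.
#' @param header character vector of comment lines (written as `# <line>`).
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline TSV, skipping comment header lines
#' @param path file path.
#' @return data frame.
#' @export
read_tsv_report <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}
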