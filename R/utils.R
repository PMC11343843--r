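#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   left_join inner_join anti_join semi_join bind_rows distinct rename n
#'   row_number across all_of any_of pull
#' @importFrom tibble tibble as_tibble
#' @importFrom stats qnorm pnorm phyper rnorm runif sd setNames
#' @importFrom utils head modifyList
NULL

# site token: one-letter residue + integer position, e.g. "S473"
site_token <- function(residue, position = NULL) {
  residue <- as.character(residue)
  if (is.null(position)) return(toupper(residue))
  paste0(toupper(residue), as.integer(position))
}

# phosphosite analyte id, e.g. "AKT1_S473"
site_key <- function(gene, residue, position = NULL) {
  paste(gene, site_token(residue, position), sep = "_")
}

split_site_key <- function(id) {
  m <- regmatches(id, regexec("^(.*)_([STY])(\\d+)$", id))
  tibble(
    gene_name = vapply(m, function(x) if (length(x)) x[2] else NA_character_, ""),
    residue   = vapply(m, function(x) if (length(x)) paste0(x[3], x[4]) else NA_character_, "")
  )
}

require_columns <- function(tbl, cols, what = "table") {
  missing <- setdiff(cols, names(tbl))
  if (length(missing)) {
    abort(sprintf("%s is missing mandatory column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(tbl)
}

# sign of x constrained to {-1, 0, 1} integers
sign_int <- function(x) as.integer(sign(x))

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
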