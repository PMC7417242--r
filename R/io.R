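# File formats: Genepop (3-digit alleles, one population block per sample),
# a documented CSV genotype dialect (rows = individuals, columns = loci,
# codes 0/1/2/NA), and the flat key-value parameter file.

#' Write genotypes to a Genepop file
#'
#' Biallelic 0/1/2 codes become two 3-digit alleles ("001"/"002"); missing
#' genotypes become "000000". Each element of `pops` is written as one `Pop`
#' block.
#'
#' @param pops Named list of genotype matrices (individuals x loci, shared
#'   locus set, 0/1/2/`NA`).
#' @param file Output path.
#' @param title Header line.
#' @export
write_genepop <- function(pops, file, title = "kinrecruit genotypes") {
  stopifnot(is.list(pops), length(pops) >= 1L)
  loci <- colnames(pops[[1L]])
  if (is.null(loci)) loci <- sprintf("L%03d", seq_len(ncol(pops[[1L]])))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(loci, con)
  code <- c(`0` = "001001", `1` = "001002", `2` = "002002")
  for (gm in pops) {
    writeLines("Pop", con)
    ids <- rownames(gm)
    if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(nrow(gm)))
    for (i in seq_len(nrow(gm))) {
      g <- gm[i, ]
      al <- ifelse(is.na(g), "000000", code[as.character(g)])
      writeLines(paste0(ids[i], " ,  ", paste(al, collapse = " ")), con)
    }
  }
  invisible(file)
}

#' Read genotypes from a Genepop file
#'
#' Parses the common dialect: a title line, locus names (one per line or one
#' comma-separated line), then `Pop` blocks of `id , a1a2 a1a2 ...` rows with
#' 2- or 3-digit allele codes. Biallelic loci are recoded to 0/1/2 counts of
#' the second allele code seen; "00"/"000" alleles become `NA`.
#'
#' @param file Path to a Genepop file.
#' @return Named list of genotype matrices, one per `Pop` block.
#' @export
read_genepop <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  is_pop <- toupper(lines) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop) || first_pop < 3L) {
    stop("not a Genepop file: no Pop line after title and loci", call. = FALSE)
  }
  loci_lines <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(loci_lines, ",")))
  pop_idx <- cumsum(is_pop)
  pops <- list()
  digits <- NA_integer_
  for (p in seq_len(max(pop_idx))) {
    rows <- lines[pop_idx == p & !is_pop]
    ids <- character(0)
    gm <- NULL
    alleles <- list()
    for (row in rows) {
      parts <- strsplit(row, ",")[[1L]]
      if (length(parts) < 2L) stop("malformed Genepop row: ", row, call. = FALSE)
      ids <- c(ids, trimws(parts[1L]))
      gts <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "[[:space:]]+")[[1L]]
      if (length(gts) != length(loci)) {
        stop("genotype count does not match locus count in row: ", row,
             call. = FALSE)
      }
      if (is.na(digits)) digits <- nchar(gts[1L]) / 2L
      alleles[[length(alleles) + 1L]] <-
        cbind(substr(gts, 1L, digits), substr(gts, digits + 1L, 2L * digits))
    }
    a1 <- do.call(rbind, lapply(alleles, function(x) x[, 1L]))
    a2 <- do.call(rbind, lapply(alleles, function(x) x[, 2L]))
    a1[a1 == strrep("0", digits)] <- NA
    a2[a2 == strrep("0", digits)] <- NA
    pops[[p]] <- list(a1 = a1, a2 = a2, ids = ids)
  }
  # recode per locus against the globally second-sorted allele label
  out <- lapply(pops, function(pp) {
    gm <- matrix(NA_integer_, length(pp$ids), length(loci),
                 dimnames = list(pp$ids, loci))
    gm
  })
  for (l in seq_along(loci)) {
    labs <- sort(unique(stats::na.omit(c(
      unlist(lapply(pops, function(pp) pp$a1[, l])),
      unlist(lapply(pops, function(pp) pp$a2[, l]))))))
    if (length(labs) > 2L) {
      stop(sprintf("locus %s has %d alleles; only biallelic loci are supported",
                   loci[l], length(labs)), call. = FALSE)
    }
    ref <- labs[length(labs)]  # count copies of the last-sorted allele
    for (p in seq_along(pops)) {
      a1 <- pops[[p]]$a1[, l]; a2 <- pops[[p]]$a2[, l]
      g <- (a1 == ref) + (a2 == ref)
      out[[p]][, l] <- as.integer(g)
    }
  }
  names(out) <- paste0("pop", seq_along(out))
  out
}

#' Write/read the CSV genotype dialect
#'
#' Rows are individuals (first column `id`), remaining columns are loci with
#' codes 0/1/2 and empty cells for missing calls.
#'
#' @param G Genotype matrix (individuals x loci).
#' @param file Path.
#' @return `read_genotypes_csv()` returns the genotype matrix with dimnames.
#' @export
write_genotypes_csv <- function(G, file) {
  d <- data.frame(id = rownames(G), G, check.names = FALSE)
  utils::write.csv(d, file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_genotypes_csv
#' @export
read_genotypes_csv <- function(file) {
  d <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1L] != "id") stop("first column must be 'id'", call. = FALSE)
  G <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(G) <- "integer"
  if (any(!is.na(G) & !(G %in% 0:2))) {
    stop("genotype codes must be 0, 1, 2 or missing", call. = FALSE)
  }
  rownames(G) <- d$id
  G
}

#' Default analysis parameters
#'
#' The biological and habitat parameters of the focal system, as one flat
#' named list keyed by the conventional abbreviations: colony fecundity `E`,
#' hatch rate `H`, daily hatch fraction `Hd`, pelagic survival `S`, the
#' (rounded) daily per-colony recruit output `R_Cd`, transect density `Da`
#' over area `At`, reproductive female fraction `F_R`, habitat strip lengths
#' `L_r25`/`L_r50` with width `W` for the 25/50 km source radii, the radii
#' themselves, the `daily_factor` of the forward cohort formula, the rounded
#' density `C_A_rounded` used by the inverse formulas, model `family_size`,
#' light-trap sample size `n_sample`, and the empirical accepted sibling-pair
#' count `sp_emp`.
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(E = 803, H = 0.5, Hd = 0.5, S = 0.03, R_Cd = 6,
       Da = 10.23, At = 0.1, F_R = 0.33,
       L_r25 = 160, L_r50 = 387, W = 1.2, r25 = 25, r50 = 50,
       daily_factor = 0.5, C_A_rounded = 102,
       family_size = 6, n_sample = 168, sp_emp = 48)
}

#' Read parameters from a flat key-value file
#'
#' One `key = value` pair per line (`#` comments and blank lines ignored),
#' keys restricted to those of [default_params()]; unknown keys are an error,
#' guarding against silent typos in parameter names. Values omitted from the
#' file keep their defaults.
#'
#' @param file Path to the parameter file.
#' @return Named list as [default_params()], with overrides applied.
#' @export
read_params <- function(file) {
  params <- default_params()
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed parameter line: ", ln, call. = FALSE)
    key <- trimws(kv[1L])
    if (!key %in% names(params)) {
      stop("unknown parameter key: ", key, call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(trimws(kv[2L])))
    if (is.na(val)) stop("non-numeric value for key ", key, call. = FALSE)
    params[[key]] <- val
  }
  params
}
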