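#' Construct a validated pedigree table
#'
#' Builds the central pedigree container from a data frame of individual
#' records. Parent identifiers that never appear in the `id` column are added
#' as stub founders (all-missing records flagged in the `stub` column) with a
#' warning, so that every parent link resolves.
#'
#' @param df data frame with columns `id`, `sire`, `dam` and optionally
#'   `sex` (`"female"`/`"male"`/`"unknown"`), `birth_year`, `death_year`,
#'   `birth_place`, `marriage_place`, `marriage_year`. Missing values are `NA`.
#' @return An object of class `pedigree_table`: a list with `records` (the
#'   normalized data frame, topologically ordered so parents precede
#'   offspring) and `child_index` (named list mapping parent id to offspring
#'   ids).
#' @examples
#' ped <- pedigree_table(data.frame(
#'   id = c("a", "b", "c"), sire = c(NA, "a", NA), dam = c(NA, "c", NA),
#'   sex = c("male", "female", "female")))
#' @export
pedigree_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("mandatory columns missing: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  opt <- c(sex = "unknown", birth_year = NA_integer_, death_year = NA_integer_,
           birth_place = NA_character_, marriage_place = NA_character_,
           marriage_year = NA_integer_)
  for (nm in names(opt)) if (!nm %in% names(df)) df[[nm]] <- rep(opt[[nm]], nrow(df))

  df$id <- as.character(df$id)
  df$sire <- as.character(df$sire)
  df$dam <- as.character(df$dam)
  df$sire[df$sire %in% c("", "0", "NA")] <- NA_character_
  df$dam[df$dam %in% c("", "0", "NA")] <- NA_character_
  df$sex <- normalize_sex(df$sex)
  for (nm in c("birth_year", "death_year", "marriage_year")) {
    df[[nm]] <- suppressWarnings(as.integer(df[[nm]]))
  }
  for (nm in c("birth_place", "marriage_place")) {
    v <- as.character(df[[nm]])
    v[v == ""] <- NA_character_
    df[[nm]] <- v
  }

  dup <- df$id[duplicated(df$id)]
  if (length(dup)) stop("duplicate id(s): ", paste(unique(utils::head(dup, 10)), collapse = ", "))
  self <- which(!is.na(df$sire) & df$sire == df$id | !is.na(df$dam) & df$dam == df$id)
  if (length(self)) {
    stop("individual listed as its own parent at row(s): ", paste(utils::head(self, 10), collapse = ", "))
  }
  bad_dates <- which(!is.na(df$birth_year) & !is.na(df$death_year) & df$death_year < df$birth_year)
  if (length(bad_dates)) {
    stop("death_year before birth_year at row(s): ", paste(utils::head(bad_dates, 10), collapse = ", "))
  }

  referenced <- unique(stats::na.omit(c(df$sire, df$dam)))
  missing_parents <- setdiff(referenced, df$id)
  df$stub <- rep(FALSE, nrow(df))
  if (length(missing_parents)) {
    warning(length(missing_parents), " parent id(s) absent from the id column; added as stub founders")
    stub <- df[0, ]
    stub[seq_along(missing_parents), ] <- NA
    stub$id <- missing_parents
    stub$sex <- "unknown"
    stub$stub <- TRUE
    df <- rbind(df, stub)
  }

  ord <- topo_order(df$id, df$sire, df$dam)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL

  structure(list(records = df, child_index = build_child_index(df)),
            class = "pedigree_table")
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("f", "female", "2", "w")] <- "female"
  out[x %in% c("m", "male", "1")] <- "male"
  out
}

build_child_index <- function(df) {
  par <- c(df$sire, df$dam)
  kid <- c(df$id, df$id)
  keep <- !is.na(par)
  lapply(split(kid[keep], par[keep]), unique)
}

#' Read a genealogy from delimited text
#'
#' Reads a CSV or TSV export (delimiter autodetected from the header line
#' unless given) and maps its columns onto the pedigree schema. Minimal
#' three-column files (id, sire, dam) are accepted.
#'
#' @param path file path.
#' @param dialect named list mapping schema fields (`id`, `sire`, `dam`,
#'   `sex`, `birth_year`, `death_year`, `birth_place`, `marriage_place`,
#'   `marriage_year`) to column names in the file. Fields absent from the
#'   list are looked up under their schema name.
#' @param sep field delimiter; `NULL` (default) autodetects `,` vs tab.
#' @return a [pedigree_table()].
#' @export
load_genealogy <- function(path, dialect = list(), sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           comment.char = "")
  fields <- c("id", "sire", "dam", "sex", "birth_year", "death_year",
              "birth_place", "marriage_place", "marriage_year")
  out <- list()
  for (f in fields) {
    src <- dialect[[f]] %||% f
    if (src %in% names(raw)) out[[f]] <- raw[[src]]
  }
  for (f in c("id", "sire", "dam")) {
    if (is.null(out[[f]])) stop("mandatory column not mappable: ", f)
  }
  pedigree_table(as.data.frame(out, stringsAsFactors = FALSE))
}

#' Write a genealogy to CSV
#'
#' Inverse of [load_genealogy()]: writes the normalized schema so that a
#' round-trip is lossless. Stub founders are dropped (they are reconstructed
#' on load).
#'
#' @param ped a `pedigree_table`.
#' @param path output path.
#' @export
write_genealogy <- function(ped, path) {
  df <- ped$records[!ped$records$stub, setdiff(names(ped$records), "stub"), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Summarize a pedigree
#'
#' Counts individuals, resolved maternities/paternities, unordered full-sibling
#' pairs and founders, pedigree depth, and mean sibship sizes. Depth of an
#' individual is the longest chain of known ancestors above it; `depth_base`
#' selects whether founders count as generation 0 or 1.
#'
#' @param ped a `pedigree_table`.
#' @param depth_base 1 (default) or 0; added to the raw ancestor-path length.
#' @return list of class `pedigree_summary`.
#' @export
pedigree_summary <- function(ped, depth_base = 1L) {
  df <- ped$records
  n <- nrow(df)
  if (n == 0L) {
    z <- list(n_individuals = 0L, n_maternities = 0L, n_paternities = 0L,
              n_fullsib_pairs = 0L, n_founders = 0L, mean_depth = 0,
              max_depth = 0, mean_maternal_sibship = 0, mean_paternal_sibship = 0)
    return(structure(z, class = "pedigree_summary"))
  }
  n_mat <- sum(!is.na(df$dam))
  n_pat <- sum(!is.na(df$sire))
  both <- !is.na(df$sire) & !is.na(df$dam)
  fs_counts <- table(paste(df$sire[both], df$dam[both], sep = "\r"))
  n_fs <- sum(choose(as.integer(fs_counts), 2))
  founders <- is.na(df$sire) & is.na(df$dam)

  # records are in topological order, so one forward pass suffices
  idx <- seq_len(n); names(idx) <- df$id
  depth <- integer(n)
  si <- unname(idx[df$sire]); di <- unname(idx[df$dam])
  for (i in seq_len(n)) {
    d <- -1L
    if (!is.na(si[i])) d <- max(d, depth[si[i]])
    if (!is.na(di[i])) d <- max(d, depth[di[i]])
    depth[i] <- d + 1L
  }
  mat_sib <- table(df$dam[!is.na(df$dam)])
  pat_sib <- table(df$sire[!is.na(df$sire)])
  structure(list(
    n_individuals = n,
    n_maternities = n_mat,
    n_paternities = n_pat,
    n_fullsib_pairs = as.integer(n_fs),
    n_founders = sum(founders),
    mean_depth = mean(depth) + depth_base,
    max_depth = max(depth) + depth_base,
    mean_maternal_sibship = if (length(mat_sib)) mean(mat_sib) else 0,
    mean_paternal_sibship = if (length(pat_sib)) mean(pat_sib) else 0
  ), class = "pedigree_summary")
}

#' @export
print.pedigree_summary <- function(x, ...) {
  cat(sprintf(
    "pedigree: %d individuals, %d maternities, %d paternities, %d full-sib pairs\n",
    x$n_individuals, x$n_maternities, x$n_paternities, x$n_fullsib_pairs))
  cat(sprintf("founders: %d; depth mean %.1f, max %d; sibship mean %.2f (maternal) %.2f (paternal)\n",
              x$n_founders, x$mean_depth, as.integer(x$max_depth),
              x$mean_maternal_sibship, x$mean_paternal_sibship))
  invisible(x)
}

#' @export
print.pedigree_table <- function(x, ...) {
  cat(sprintf("<pedigree_table: %d individuals (%d stubs), %d parents with offspring>\n",
              nrow(x$records), sum(x$records$stub), length(x$child_index)))
  invisible(x)
}

#' All descendants of a focal individual
#'
#' Transitive closure over the child index, excluding the focal itself.
#'
#' @param ped a `pedigree_table`.
#' @param focal individual id.
#' @return character vector of descendant ids (possibly empty).
#' @export
descendants <- function(ped, focal) {
  if (!focal %in% ped$records$id) stop("unknown focal id: ", focal)
  out <- character(0)
  frontier <- focal
  while (length(frontier)) {
    kids <- unique(unlist(ped$child_index[frontier], use.names = FALSE))
    kids <- setdiff(kids, c(out, focal))
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' All known ancestors of a focal individual
#' @inheritParams descendants
#' @return character vector of ancestor ids (possibly empty).
#' @export
ancestors <- function(ped, focal) {
  df <- ped$records
  if (!focal %in% df$id) stop("unknown focal id: ", focal)
  idx <- seq_len(nrow(df)); names(idx) <- df$id
  out <- character(0)
  frontier <- focal
  while (length(frontier)) {
    i <- idx[frontier]
    pars <- unique(stats::na.omit(c(df$sire[i], df$dam[i])))
    pars <- setdiff(pars, out)
    out <- c(out, pars)
    frontier <- pars
  }
  setdiff(out, focal)
}
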