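#' Construct and validate a pedigree
#'
#' A pedigree is a set of individuals linked to their parents within
#' families. Founders are individuals with both parents unknown; the
#' both-or-neither rule is enforced (an individual with exactly one known
#' parent is rejected unless dummy parents are requested), parent links
#' must be acyclic, referenced parents must exist and have the right sex,
#' and every family must contain at least one founder.
#'
#' @param df data.frame with columns `fid`, `id`, `father`, `mother`,
#'   `sex`, where unknown parents are `NA` and `sex` is `"male"` or
#'   `"female"` (numeric 1/2 is also accepted). Optional columns
#'   `generation`, `birth_year`, `vital_status` ("alive"/"dead"),
#'   `age_years` and any further annotation columns are carried along.
#' @param add_dummy_parents if `TRUE`, an individual with exactly one known
#'   parent has the missing parent auto-created as a founder instead of
#'   triggering an error.
#' @return An object of class `pedigree`: a data.frame as above with ids
#'   coerced to character and sex stored symbolically.
#' @export
pedigree <- function(df, add_dummy_parents = FALSE) {
  req <- c("fid", "id", "father", "mother", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("pedigree is missing required columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("fid", "id", "father", "mother"))
    df[[col]] <- as.character(df[[col]])
  df$sex <- decode_sex(df$sex)

  key <- paste(df$fid, df$id, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup) > 0)
    stop("duplicate person id(s) within family: ",
         paste(unique(gsub("\r", "/", dup)), collapse = ", "))

  one_parent <- xor(is.na(df$father), is.na(df$mother))
  if (any(one_parent)) {
    if (!add_dummy_parents)
      stop("individual(s) with exactly one known parent (both-or-neither rule): ",
           paste(df$id[one_parent], collapse = ", "),
           ". Use add_dummy_parents = TRUE to auto-complete.")
    df <- add_dummy_parent_rows(df, one_parent)
    key <- paste(df$fid, df$id, sep = "\r")
  }

  for (fam in unique(df$fid)) {
    sub <- df[df$fid == fam, , drop = FALSE]
    validate_family(sub, fam)
  }

  if (!is.null(df$age_years)) {
    bad <- !is.na(df$age_years) & df$age_years < 0
    if (any(bad))
      stop("negative age_years for: ", paste(df$id[bad], collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

decode_sex <- function(x) {
  if (is.numeric(x)) x <- as.character(x)
  x <- tolower(as.character(x))
  out <- ifelse(x %in% c("1", "m", "male"), "male",
         ifelse(x %in% c("2", "f", "female"), "female", NA_character_))
  if (anyNA(out))
    stop("sex must be coded 1/2, M/F or male/female; offending values: ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

add_dummy_parent_rows <- function(df, one_parent) {
  new <- list()
  for (i in which(one_parent)) {
    dummy <- paste0("dummy_", df$id[i])
    if (is.na(df$father[i])) {
      df$father[i] <- dummy
      sx <- "male"
    } else {
      df$mother[i] <- dummy
      sx <- "female"
    }
    row <- df[i, , drop = FALSE]
    row$id <- dummy; row$father <- NA_character_; row$mother <- NA_character_
    row$sex <- sx
    for (col in setdiff(names(df), c("fid", "id", "father", "mother", "sex")))
      row[[col]] <- NA
    new[[length(new) + 1L]] <- row
  }
  rbind(df, do.call(rbind, new))
}

validate_family <- function(sub, fam) {
  ids <- sub$id
  for (side in c("father", "mother")) {
    ref <- sub[[side]]
    known <- !is.na(ref)
    bad <- known & !(ref %in% ids)
    if (any(bad))
      stop("family ", fam, ": unknown ", side, " id ",
           paste(unique(ref[bad]), collapse = ", "), " referenced by ",
           paste(sub$id[bad], collapse = ", "))
    psex <- sub$sex[match(ref[known], ids)]
    want <- if (side == "father") "male" else "female"
    wrong <- psex != want
    if (any(wrong))
      stop("family ", fam, ": ", side, " id(s) ",
           paste(unique(ref[known][wrong]), collapse = ", "),
           " are not ", want)
  }
  founder <- is.na(sub$father) & is.na(sub$mother)
  if (!any(founder))
    stop("family ", fam, ": no founder (every individual has parents; ",
         "parent links cannot be acyclic)")
  ord <- peel_order(sub)
  if (anyNA(ord)) {
    stuck <- ids[!(ids %in% ids[stats::na.omit(ord)])]
    stop("family ", fam, ": cycle in parent links involving: ",
         paste(stuck, collapse = ", "))
  }
  invisible(TRUE)
}

# Topological order of one family: parents before children; NA if a cycle
# prevents completion.
peel_order <- function(sub) {
  ids <- sub$id
  placed <- rep(FALSE, length(ids))
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(sub$father) | sub$father %in% ids[placed]) &
      (is.na(sub$mother) | sub$mother %in% ids[placed])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) return(NA_integer_)
  ord
}

#' Read a PED/FAM-style pedigree file
#'
#' Whitespace- or tab-delimited, first five columns fixed as
#' `FID IID PAT MAT SEX`; an optional header row names additional study
#' columns, which are preserved as annotations. Unknown parents are coded
#' by `missing_marker` (default `"0"`, the PED convention); sex is coded
#' 1 = male, 2 = female on input.
#'
#' @param path file path.
#' @param missing_marker string coding an unknown parent.
#' @param add_dummy_parents see [pedigree()].
#' @return A [pedigree()] object.
#' @export
read_ped <- function(path, missing_marker = "0", add_dummy_parents = FALSE) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  first <- readLines(path, n = 1L)
  fields <- strsplit(trimws(first), "[ \t]+")[[1]]
  has_header <- length(fields) >= 5 &&
    any(grepl("^(fid|iid|pat|mat|sex|family|individual|father|mother)$",
              tolower(fields[1:5])))
  tab <- utils::read.table(path, header = has_header,
                           colClasses = "character",
                           stringsAsFactors = FALSE,
                           comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(tab) < 5)
    stop("pedigree file must have at least 5 columns (FID IID PAT MAT SEX)")
  names(tab)[1:5] <- c("fid", "id", "father", "mother", "sex")
  tab$father[tab$father == missing_marker] <- NA_character_
  tab$mother[tab$mother == missing_marker] <- NA_character_
  for (col in intersect(c("birth_year", "age_years"), names(tab)))
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  pedigree(tab, add_dummy_parents = add_dummy_parents)
}

#' Write a pedigree to a PED-style file
#'
#' @param ped a [pedigree()] object.
#' @param path output path.
#' @param missing_marker marker written for unknown parents.
#' @export
write_ped <- function(ped, path, missing_marker = "0") {
  stopifnot(inherits(ped, "pedigree"))
  out <- as.data.frame(ped)
  out$father[is.na(out$father)] <- missing_marker
  out$mother[is.na(out$mother)] <- missing_marker
  out$sex <- ifelse(out$sex == "male", "1", "2")
  names(out)[1:5] <- c("FID", "IID", "PAT", "MAT", "SEX")
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Founder indicator
#'
#' @param ped a [pedigree()] object.
#' @return Logical vector, `TRUE` where both parents are unknown.
#' @export
is_founder <- function(ped) {
  is.na(ped$father) & is.na(ped$mother)
}

#' @method print pedigree
#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", length(unique(x$fid)), "family(ies),",
      nrow(x), "individuals,", sum(is_founder(x)), "founders\n")
  invisible(x)
}
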