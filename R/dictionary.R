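# Ophthalmic drug-class dictionary. Generic names are the join key between
# claims and pharmacology: each entry carries its IOP-lowering class(es)
# (PG prostaglandin analog, BB beta-blocker, CAI carbonic anhydrase
# inhibitor, AA alpha2-agonist), whether it is a fixed combination (two
# classes co-formulated in one bottle), the approved unit bottle volume
# (2.5 mL for once-daily products, 5 mL otherwise) and dosing frequency.
# The shipped file covers the common Japanese glaucoma eye drops and is
# user-extensible: point read_drug_dictionary() at an edited copy.

#' IOP-lowering drug classes in canonical order
#'
#' @return Character vector `c("PG", "BB", "CAI", "AA")`.
#' @export
drug_classes <- function() c("PG", "BB", "CAI", "AA")

order_classes <- function(x) x[order(match(x, drug_classes()))]

#' Read a drug dictionary file
#'
#' The dictionary is a delimited text file (comma or tab, auto-detected) with
#' columns `generic_name`, `class1`, `class2` (empty for monotherapy
#' products), `is_fixed_combination`, `unit_bottle_volume` (mL) and
#' `dosing_frequency` (`once_daily` or `twice_or_more_daily`).
#'
#' @param path Path to the dictionary file.
#' @return A data.frame, validated: fixed combinations carry exactly two
#'   classes, monotherapies exactly one, and the unit bottle volume is 2.5 mL
#'   for once-daily products and 5 mL otherwise.
#' @export
read_drug_dictionary <- function(path) {
  d <- read_delim_auto(path)
  need <- c("generic_name", "class1", "class2", "is_fixed_combination",
            "unit_bottle_volume", "dosing_frequency")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("dictionary is missing columns: ", paste(miss, collapse = ", "))
  d$class2[is.na(d$class2) | d$class2 == ""] <- NA_character_
  d$is_fixed_combination <- as.logical(d$is_fixed_combination)
  bad <- !d$class1 %in% drug_classes() |
    (!is.na(d$class2) & !d$class2 %in% drug_classes())
  if (any(bad)) stop("unknown drug class for: ", paste(d$generic_name[bad], collapse = ", "))
  if (any(d$is_fixed_combination != !is.na(d$class2)))
    stop("fixed-combination entries must carry exactly two classes, monotherapies one")
  if (any(!is.na(d$class2) & d$class1 == d$class2))
    stop("fixed-combination entries must combine two distinct classes")
  vol_ok <- ifelse(d$dosing_frequency == "once_daily",
                   d$unit_bottle_volume == 2.5, d$unit_bottle_volume == 5)
  if (!all(vol_ok))
    stop("unit bottle volume must be 2.5 mL for once-daily and 5 mL for twice-or-more-daily products")
  if (anyDuplicated(d$generic_name)) stop("duplicated generic_name in dictionary")
  d
}

.dict_cache <- new.env(parent = emptyenv())

#' The shipped drug dictionary
#'
#' @return The default dictionary bundled with the package (see
#'   [read_drug_dictionary()] for the format).
#' @export
drug_dictionary <- function() {
  if (is.null(.dict_cache$dict)) {
    path <- system.file("extdata", "drug_dictionary.csv", package = "pdcpersist")
    .dict_cache$dict <- read_drug_dictionary(path)
  }
  .dict_cache$dict
}

#' Resolve generic names against a dictionary
#'
#' @param generic_names Character vector of product names.
#' @param dictionary A drug dictionary data.frame.
#' @return The matching dictionary rows, one per input element. Unresolvable
#'   names are a hard error listing the offending names.
#' @export
resolve_drug <- function(generic_names, dictionary = drug_dictionary()) {
  i <- match(generic_names, dictionary$generic_name)
  if (anyNA(i)) {
    stop("generic names not in the drug dictionary: ",
         paste(sort(unique(generic_names[is.na(i)])), collapse = ", "))
  }
  dictionary[i, , drop = FALSE]
}

#' Classify a concurrently supplied set of products into a regimen label
#'
#' Labels follow the two-drug second-line taxonomy: `monotherapy:<class>`,
#' `fixed:<c1>/<c2>` (one co-formulated product), `unfixed:<c1>+<c2>` (two
#' separate single-class products), `triple` (three distinct classes) or
#' `other`. Class pairs are ordered canonically (PG, BB, CAI, AA).
#'
#' @param generic_names Products supplied concurrently (order irrelevant).
#' @param dictionary A drug dictionary data.frame.
#' @return A single regimen label string.
#' @export
classify_regimen <- function(generic_names, dictionary = drug_dictionary()) {
  generic_names <- unique(generic_names)
  if (length(generic_names) == 0L) stop("cannot classify an empty product set")
  e <- resolve_drug(generic_names, dictionary)
  cls <- order_classes(unique(c(e$class1, e$class2[!is.na(e$class2)])))
  nfix <- sum(e$is_fixed_combination)
  if (length(cls) == 1L) return(paste0("monotherapy:", cls))
  if (length(cls) == 2L) {
    if (nfix >= 1L) {
      # a co-formulated product delivers the pair; extra same-pair products
      # (e.g. a leftover component bottle) do not change the class pair
      return(paste0("fixed:", cls[1L], "/", cls[2L]))
    }
    return(paste0("unfixed:", cls[1L], "+", cls[2L]))
  }
  if (length(cls) == 3L) return("triple")
  "other"
}

regimen_classes <- function(label) {
  body <- sub("^[a-z_]+:", "", label)
  strsplit(body, "[/+]")[[1L]]
}
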