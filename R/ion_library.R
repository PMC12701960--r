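## Catalog of built-in diagnostic ions.
##
## Each entry: name, composition (residue counts), optional losses/adducts,
## and a group tag. m/z values are derived through oxonium_mz() at catalog
## construction, never stored, so the catalog can't drift from the mass
## engine.

.comp <- function(...) {
  x <- c(...)
  storage.mode(x) <- "integer"
  x
}

.catalog_entries <- function() {
  e <- function(name, composition, group, losses = NULL, adducts = NULL)
    list(name = name, composition = composition, losses = losses,
         adducts = adducts, group = group)
  list(
    ## HexNAc-derived fragment ladder
    e("HexNAc-C2H6O3", .comp(HexNAc = 1), "HexNAc-derived", losses = "C2H6O3"),
    e("HexNAc-CH6O3",  .comp(HexNAc = 1), "HexNAc-derived", losses = "CH6O3"),
    e("HexNAc-C2H4O2", .comp(HexNAc = 1), "HexNAc-derived", losses = "C2H4O2"),
    e("HexNAc-2H2O",   .comp(HexNAc = 1), "HexNAc-derived", losses = c("H2O", "H2O")),
    e("HexNAc-H2O",    .comp(HexNAc = 1), "HexNAc-derived", losses = "H2O"),
    e("HexNAc",        .comp(HexNAc = 1), "HexNAc-derived"),
    ## Hex-derived
    e("Hex-2H2O", .comp(Hex = 1), "Hex-derived", losses = c("H2O", "H2O")),
    e("Hex-H2O",  .comp(Hex = 1), "Hex-derived", losses = "H2O"),
    e("Hex",      .comp(Hex = 1), "Hex-derived"),
    ## Deoxyhexose (fucose)
    e("dHex-H2O", .comp(dHex = 1), "Hex-derived", losses = "H2O"),
    e("dHex",     .comp(dHex = 1), "Hex-derived"),
    ## Pentose
    e("Pent-H2O", .comp(Pent = 1), "Hex-derived", losses = "H2O"),
    e("Pent",     .comp(Pent = 1), "Hex-derived"),
    ## Sialic acids and acetylated variants
    e("NeuAc-2H2O",    .comp(NeuAc = 1), "sialic-acid", losses = c("H2O", "H2O")),
    e("NeuAc-H2O",     .comp(NeuAc = 1), "sialic-acid", losses = "H2O"),
    e("NeuAc",         .comp(NeuAc = 1), "sialic-acid"),
    e("NeuAc[Ac]-H2O", .comp(NeuAc = 1, Acetyl = 1), "sialic-acid", losses = "H2O"),
    e("NeuAc[Ac]",     .comp(NeuAc = 1, Acetyl = 1), "sialic-acid"),
    e("NeuGc-H2O",     .comp(NeuGc = 1), "sialic-acid", losses = "H2O"),
    e("NeuGc",         .comp(NeuGc = 1), "sialic-acid"),
    e("NeuGc[Ac]-H2O", .comp(NeuGc = 1, Acetyl = 1), "sialic-acid", losses = "H2O"),
    e("NeuGc[Ac]",     .comp(NeuGc = 1, Acetyl = 1), "sialic-acid"),
    ## Phosphorylated (mannose-6-phosphate epitopes) and sulfated
    e("Hex-Phospho",    .comp(Hex = 1, Phospho = 1), "phospho"),
    e("Hex2-Phospho",   .comp(Hex = 2, Phospho = 1), "phospho"),
    e("HexNAc-Phospho", .comp(HexNAc = 1, Phospho = 1), "phospho"),
    e("HexNAc-Sulfo",   .comp(HexNAc = 1, Sulfo = 1), "phospho"),
    ## Oligosaccharides
    e("Hex-dHex",                 .comp(Hex = 1, dHex = 1), "oligosaccharide"),
    e("Hex2",                     .comp(Hex = 2), "oligosaccharide"),
    e("HexNAc-dHex",              .comp(HexNAc = 1, dHex = 1), "oligosaccharide"),
    e("Hex-HexNAc-H2O",           .comp(Hex = 1, HexNAc = 1), "oligosaccharide", losses = "H2O"),
    e("Hex-HexNAc",               .comp(Hex = 1, HexNAc = 1), "oligosaccharide"),
    e("HexNAc2",                  .comp(HexNAc = 2), "oligosaccharide"),
    e("NeuAc-Hex",                .comp(NeuAc = 1, Hex = 1), "oligosaccharide"),
    e("NeuGc-Hex",                .comp(NeuGc = 1, Hex = 1), "oligosaccharide"),
    e("Hex3",                     .comp(Hex = 3), "oligosaccharide"),
    e("NeuAc-HexNAc",             .comp(NeuAc = 1, HexNAc = 1), "oligosaccharide"),
    e("NeuGc-HexNAc",             .comp(NeuGc = 1, HexNAc = 1), "oligosaccharide"),
    e("Hex-HexNAc-dHex",          .comp(Hex = 1, HexNAc = 1, dHex = 1), "oligosaccharide"),
    e("Hex2-HexNAc",              .comp(Hex = 2, HexNAc = 1), "oligosaccharide"),
    e("Hex-HexNAc2",              .comp(Hex = 1, HexNAc = 2), "oligosaccharide"),
    e("NeuAc2",                   .comp(NeuAc = 2), "oligosaccharide"),
    e("HexNAc3",                  .comp(HexNAc = 3), "oligosaccharide"),
    e("NeuAc-Hex-HexNAc",         .comp(NeuAc = 1, Hex = 1, HexNAc = 1), "oligosaccharide"),
    e("NeuGc-Hex-HexNAc",         .comp(NeuGc = 1, Hex = 1, HexNAc = 1), "oligosaccharide"),
    e("Hex2-HexNAc-dHex",         .comp(Hex = 2, HexNAc = 1, dHex = 1), "oligosaccharide"),
    e("Hex3-HexNAc",              .comp(Hex = 3, HexNAc = 1), "oligosaccharide"),
    e("Hex2-HexNAc2",             .comp(Hex = 2, HexNAc = 2), "oligosaccharide"),
    e("NeuAc-Hex-HexNAc-dHex",    .comp(NeuAc = 1, Hex = 1, HexNAc = 1, dHex = 1), "oligosaccharide"),
    e("NeuGc-Hex-HexNAc-dHex",    .comp(NeuGc = 1, Hex = 1, HexNAc = 1, dHex = 1), "oligosaccharide"),
    e("Hex2-HexNAc2-dHex",        .comp(Hex = 2, HexNAc = 2, dHex = 1), "oligosaccharide"),
    e("Hex3-HexNAc2",             .comp(Hex = 3, HexNAc = 2), "oligosaccharide"),
    e("NeuAc2-Hex-HexNAc",        .comp(NeuAc = 2, Hex = 1, HexNAc = 1), "oligosaccharide"),
    ## m/z 964.33 in the literature; composition NeuAc+NeuGc reproduces it
    e("NeuAc-NeuGc-Hex-HexNAc",   .comp(NeuAc = 1, NeuGc = 1, Hex = 1, HexNAc = 1), "oligosaccharide"),
    e("NeuGc2-Hex-HexNAc",        .comp(NeuGc = 2, Hex = 1, HexNAc = 1), "oligosaccharide"),
    e("NeuAc2-Hex2-HexNAc2",      .comp(NeuAc = 2, Hex = 2, HexNAc = 2), "oligosaccharide")
  )
}

## The 17-ion "common" screening set (the full membership is configurable;
## this default is the most widely used ions among those the catalog names).
.COMMON_IONS <- c(
  "HexNAc-CH6O3", "HexNAc-C2H4O2", "Hex", "HexNAc-2H2O", "HexNAc-H2O",
  "HexNAc", "NeuAc-H2O", "NeuGc-H2O", "NeuAc", "NeuGc",
  "Hex-HexNAc", "NeuAc-Hex", "NeuAc-HexNAc", "Hex-HexNAc-dHex",
  "Hex2-HexNAc", "NeuAc-Hex-HexNAc", "NeuGc-Hex-HexNAc"
)

.new_ion_selection <- function(name, mz, group, composition, losses, adducts,
                               label) {
  stopifnot(length(name) == length(mz))
  if (anyDuplicated(name))
    stop("duplicate ion names in selection: ",
         paste(unique(name[duplicated(name)]), collapse = ", "),
         call. = FALSE)
  dup_mz <- duplicated(round(mz, 4))
  if (any(dup_mz))
    message("note: ", sum(dup_mz), " ion(s) share an m/z with another entry")
  out <- data.frame(name = name, mz = mz, group = group,
                    stringsAsFactors = FALSE)
  out$composition <- composition
  out$losses <- losses
  out$adducts <- adducts
  attr(out, "label") <- label
  class(out) <- c("ion_selection", "data.frame")
  out
}

#' Built-in diagnostic-ion catalog
#'
#' Returns the shipped oxonium-ion catalog as an ion selection. The
#' `"common"` set holds the 17 ions used for routine screening; `"all"`
#' returns the full catalog (56 ions) spanning HexNAc/Hex fragment
#' ladders, sialic acids and their acetylated variants, phosphorylated
#' and sulfated monosaccharides, and di- to tetrasaccharide B-ions.
#'
#' @param selection `"common"` or `"all"`.
#' @return An `ion_selection`: a data frame with columns `name`, `mz`
#'   (derived from composition at call time), `group`, and list-columns
#'   `composition`, `losses`, `adducts`; ordered by ascending m/z.
#' @examples
#' nrow(builtin_catalog("common"))  # 17
#' nrow(builtin_catalog("all"))     # >= 50
#' @export
builtin_catalog <- function(selection = c("common", "all")) {
  selection <- match.arg(selection)
  entries <- .catalog_entries()
  name <- vapply(entries, `[[`, character(1), "name")
  mz <- vapply(entries, function(x)
    oxonium_mz(x$composition, x$losses, x$adducts), numeric(1))
  group <- vapply(entries, `[[`, character(1), "group")
  sel <- .new_ion_selection(
    name, mz, group,
    composition = lapply(entries, `[[`, "composition"),
    losses = lapply(entries, `[[`, "losses"),
    adducts = lapply(entries, `[[`, "adducts"),
    label = selection
  )
  if (selection == "common") {
    sel <- sel[match(.COMMON_IONS, sel$name), , drop = FALSE]
    attr(sel, "label") <- "common"
    class(sel) <- c("ion_selection", "data.frame")
  }
  sel <- sel[order(sel$mz), , drop = FALSE]
  rownames(sel) <- NULL
  class(sel) <- c("ion_selection", "data.frame")
  sel
}

#' @export
print.ion_selection <- function(x, ...) {
  cat("Ion selection '", attr(x, "label"), "': ", nrow(x), " ions, m/z ",
      format(round(min(x$mz), 3)), "-", format(round(max(x$mz), 3)), "\n",
      sep = "")
  print(data.frame(name = x$name, mz = round(x$mz, 5), group = x$group), ...)
  invisible(x)
}

.parse_composition_string <- function(s) {
  ## "Hex:2,HexNAc:1" or "Hex2-HexNAc" style
  s <- trimws(s)
  if (!nzchar(s)) return(NULL)
  if (grepl(":", s, fixed = TRUE)) {
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    kv <- strsplit(trimws(parts), ":", fixed = TRUE)
    nm <- vapply(kv, `[[`, character(1), 1L)
    n <- as.integer(vapply(kv, function(p) if (length(p) > 1) p[[2]] else "1",
                           character(1)))
  } else {
    parts <- strsplit(s, "-", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^([A-Za-z\\[\\]]+)([0-9]*)$", parts))
    bad <- vapply(m, length, integer(1)) != 3L
    if (any(bad))
      stop("unparsable composition token: '", parts[bad][1], "'",
           call. = FALSE)
    nm <- vapply(m, `[[`, character(1), 2L)
    n <- as.integer(vapply(m, function(x) if (nzchar(x[[3]])) x[[3]] else "1",
                           character(1)))
  }
  stats::setNames(n, nm)
}

#' Read a custom-ion table
#'
#' Parses a tab-delimited custom-ion file with a header row. Each row
#' names an ion and gives either an explicit `mz` or a `composition`
#' (residue counts such as `Hex:1,HexNAc:1` or `Hex-HexNAc`), with
#' optional `losses` and `adducts` columns holding semicolon-separated
#' elemental formulas.
#'
#' @param path Path to the TSV file.
#' @return An `ion_selection` labelled `"custom"` (empty, with a warning,
#'   for a file with no data rows).
#' @export
parse_custom_ions <- function(path) {
  if (!file.exists(path)) stop("custom-ion file not found: ", path,
                               call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  names(tab) <- tolower(trimws(names(tab)))
  if (!"name" %in% names(tab))
    stop("custom-ion file must have a 'name' column: ", path, call. = FALSE)
  if (nrow(tab) == 0L) {
    warning("custom-ion file has no data rows: ", path, call. = FALSE)
    return(.new_ion_selection(character(0), numeric(0), character(0),
                              list(), list(), list(), "custom"))
  }
  n <- nrow(tab)
  name <- trimws(as.character(tab$name))
  mz <- numeric(n); comp <- vector("list", n)
  losses <- vector("list", n); adducts <- vector("list", n)
  split_formulas <- function(s) {
    if (is.null(s) || is.na(s) || !nzchar(trimws(s))) return(NULL)
    trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  }
  for (i in seq_len(n)) {
    line <- i + 1L  # header is line 1
    if (!nzchar(name[i]))
      stop("custom-ion file line ", line, ": missing ion name", call. = FALSE)
    explicit <- if ("mz" %in% names(tab)) suppressWarnings(as.numeric(tab$mz[i])) else NA_real_
    comp_str <- if ("composition" %in% names(tab)) as.character(tab$composition[i]) else ""
    has_comp <- !is.na(comp_str) && nzchar(trimws(comp_str))
    ok <- tryCatch({
      if (!is.na(explicit)) {
        if (explicit <= .PROTON_MASS)
          stop("explicit m/z ", explicit, " not above the proton mass")
        mz[i] <- explicit
      } else if (has_comp) {
        comp[i] <- list(.parse_composition_string(comp_str))
        losses[i] <- list(split_formulas(if ("losses" %in% names(tab)) tab$losses[i] else NULL))
        adducts[i] <- list(split_formulas(if ("adducts" %in% names(tab)) tab$adducts[i] else NULL))
        mz[i] <- oxonium_mz(comp[[i]], losses[[i]], adducts[[i]])
      } else {
        stop("row gives neither an m/z nor a composition")
      }
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("custom-ion file line ", line, " ('", name[i], "'): ",
           conditionMessage(ok), call. = FALSE)
  }
  .new_ion_selection(name, mz, rep("custom", n), comp, losses, adducts,
                     "custom")
}

#' Combine ion selections
#'
#' Concatenates two or more ion selections (for example the built-in
#' common set plus a custom upload) into one, preserving order and
#' rejecting duplicate names.
#'
#' @param ... `ion_selection` objects.
#' @return A combined `ion_selection` labelled `"mixed"`.
#' @export
combine_ions <- function(...) {
  sels <- list(...)
  stopifnot(length(sels) >= 1L)
  .new_ion_selection(
    unlist(lapply(sels, `[[`, "name")),
    unlist(lapply(sels, `[[`, "mz")),
    unlist(lapply(sels, `[[`, "group")),
    do.call(c, lapply(sels, `[[`, "composition")),
    do.call(c, lapply(sels, `[[`, "losses")),
    do.call(c, lapply(sels, `[[`, "adducts")),
    "mixed"
  )
}
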