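## Accessors and show methods.  Slot access stays inside the package;
## user code goes through these.

#' Accessors for domain, history and field objects
#'
#' @param x an object of the documented class.
#' @param day integer day index (0-based) for history accessors.
#' @return `gridSpec` returns the [GridSpec-class]; `regionMap` the integer
#'   region matrix; the mask accessors logical matrices; `nDays` the number of
#'   day records; `dayRecord` one day's `list(material, fields, phenotype)`;
#'   `phenotypeDay`/`materialDay`/`fieldsDay` the corresponding components;
#'   `caseId` the case identifier; `isSurrogate` whether the history came from
#'   the neural rollout.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))
#' @rdname accessors
#' @export
setMethod("gridSpec", "ImplantDomain", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("gridSpec", "HealingHistory", function(x) x@domain@grid)

#' @rdname accessors
#' @export
setGeneric("regionMap", function(x) standardGeneric("regionMap"))
#' @rdname accessors
#' @export
setMethod("regionMap", "ImplantDomain", function(x) x@region)

#' @rdname accessors
#' @export
setGeneric("implantMask", function(x) standardGeneric("implantMask"))
#' @rdname accessors
#' @export
setMethod("implantMask", "ImplantDomain",
          function(x) x@region == regionCodes()[["implant"]])

#' @rdname accessors
#' @export
setGeneric("callusMask", function(x) standardGeneric("callusMask"))
#' @rdname accessors
#' @export
setMethod("callusMask", "ImplantDomain",
          function(x) x@region == regionCodes()[["callus"]])

#' @rdname accessors
#' @export
setGeneric("cellOriginMask", function(x) standardGeneric("cellOriginMask"))
#' @rdname accessors
#' @export
setMethod("cellOriginMask", "ImplantDomain", function(x) x@cellOriginMask)

#' @rdname accessors
#' @export
setGeneric("loadMask", function(x) standardGeneric("loadMask"))
#' @rdname accessors
#' @export
setMethod("loadMask", "ImplantDomain", function(x) x@loadMask)

#' @rdname accessors
#' @export
setGeneric("firstThreadRow", function(x) standardGeneric("firstThreadRow"))
#' @rdname accessors
#' @export
setMethod("firstThreadRow", "ImplantDomain", function(x) x@firstThreadRow)

#' @rdname accessors
#' @export
setGeneric("implantParams", function(x) standardGeneric("implantParams"))
#' @rdname accessors
#' @export
setMethod("implantParams", "ImplantDomain", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("nDays", function(x) standardGeneric("nDays"))
#' @rdname accessors
#' @export
setMethod("nDays", "HealingHistory", function(x) length(x@days))

#' @rdname accessors
#' @export
setGeneric("dayRecord", function(x, day) standardGeneric("dayRecord"))
#' @rdname accessors
#' @export
setMethod("dayRecord", "HealingHistory", function(x, day) {
  key <- paste0("day", day)
  if (is.null(x@days[[key]]))
    stop("history has no record for day ", day)
  x@days[[key]]
})

#' @rdname accessors
#' @export
setGeneric("phenotypeDay", function(x, day) standardGeneric("phenotypeDay"))
#' @rdname accessors
#' @export
setMethod("phenotypeDay", "HealingHistory",
          function(x, day) dayRecord(x, day)$phenotype)

#' @rdname accessors
#' @export
setGeneric("materialDay", function(x, day) standardGeneric("materialDay"))
#' @rdname accessors
#' @export
setMethod("materialDay", "HealingHistory",
          function(x, day) dayRecord(x, day)$material)

#' @rdname accessors
#' @export
setGeneric("fieldsDay", function(x, day) standardGeneric("fieldsDay"))
#' @rdname accessors
#' @export
setMethod("fieldsDay", "HealingHistory",
          function(x, day) dayRecord(x, day)$fields)

#' @rdname accessors
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))
#' @rdname accessors
#' @export
setMethod("caseId", "HealingHistory", function(x) x@caseId)

#' @rdname accessors
#' @export
setGeneric("isSurrogate", function(x) standardGeneric("isSurrogate"))
#' @rdname accessors
#' @export
setMethod("isSurrogate", "HealingHistory", function(x) x@surrogate)

#' @rdname accessors
#' @export
setGeneric("domain", function(x) standardGeneric("domain"))
#' @rdname accessors
#' @export
setMethod("domain", "HealingHistory", function(x) x@domain)

#' @rdname accessors
#' @export
setGeneric("phenotypeMatrix", function(x) standardGeneric("phenotypeMatrix"))
#' @rdname accessors
#' @export
setMethod("phenotypeMatrix", "PhenotypeMap", function(x) x@codes)

## ---- show methods -----------------------------------------------------------

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d pixels, %.4g mm/pixel\n",
              object@nrow, object@ncol, object@pixelSize))
})

setMethod("show", "ImplantDomain", function(object) {
  tab <- table(factor(object@region, levels = regionCodes(),
                      labels = names(regionCodes())))
  cat(sprintf("ImplantDomain on a %d x %d grid (%.4g mm/pixel)\n",
              object@grid@nrow, object@grid@ncol, object@grid@pixelSize))
  cat("  pixels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  first thread row: %s; load pixels: %d; cell-origin pixels: %d\n",
              ifelse(is.na(object@firstThreadRow), "NA",
                     object@firstThreadRow),
              sum(object@loadMask), sum(object@cellOriginMask)))
})

setMethod("show", "MaterialField", function(object) {
  cat(sprintf("MaterialField %d x %d | E in [%.3g, %.3g] MPa, mean n = %.3f\n",
              nrow(object@E), ncol(object@E), min(object@E), max(object@E),
              mean(object@n)))
})

setMethod("show", "PhysicalFields", function(object) {
  cat(sprintf(
    "PhysicalFields %d x %d | |eps| max %.3g, |v| max %.3g um/s\n",
    nrow(object@eps1), ncol(object@eps1),
    max(abs(c(object@eps1, object@eps3))),
    max(sqrt(object@vx^2 + object@vy^2))))
})

setMethod("show", "PhenotypeMap", function(object) {
  codes <- phenotypeCodes()
  tab <- table(factor(object@codes, levels = codes, labels = names(codes)))
  tab <- tab[tab > 0]
  cat(sprintf("PhenotypeMap %d x %d | %s\n",
              nrow(object@codes), ncol(object@codes),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "HealingHistory", function(object) {
  cat(sprintf("HealingHistory '%s': days 0..%d (%s)\n", object@caseId,
              length(object@days) - 1L,
              if (object@surrogate) "surrogate rollout" else "simulator"))
  show(object@domain)
})

setMethod("show", "SurrogateBundle", function(object) {
  cat(sprintf(
    "SurrogateBundle | seed %s; %d training / %d test cases; forest: %s\n",
    object@meta$seed, length(object@meta$trainCases),
    length(object@meta$testCases),
    if (is.null(object@resorptionForest)) "none" else "trained"))
})
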