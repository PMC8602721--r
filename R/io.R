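## Case container, plain-text map export, JSON parameter round trips,
## config hashing and deterministic test fixtures.
##
## The case container is an RDS payload plus a JSON sidecar (schema version,
## case id, day count, grid, config hash).  No HDF5 binding is available in
## the target environment; RDS round-trips the day records bit-identically,
## and the sidecar keeps the metadata grep-able.

.CASE_SCHEMA <- "MechanoHeal-case-1"

.fnv1a <- function(txt) {
  ## 32-bit FNV-1a over the UTF-8 bytes; returned as 8-digit hex.
  ## Not cryptographic -- used only to stamp configs into artifacts.
  ## h is kept as a double in [0, 2^32); XOR via 16-bit halves because
  ## base bitwXor only covers 32-bit signed integers
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    lo <- bitwXor(h %% 65536, b %% 65536)
    hi <- bitwXor(h %/% 65536, b %/% 65536)
    ## 32x24-bit product mod 2^32, split to stay within exact doubles
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Hash a configuration list
#'
#' Stable 32-bit FNV-1a hash of the JSON serialization, embedded in every
#' artifact so outputs can be traced to the exact settings.
#'
#' @param config any JSON-serializable list.
#' @return 8-character hex string.
#' @export
configHash <- function(config) {
  .fnv1a(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                       digits = NA)))
}

#' Write / read a healing-history case container
#'
#' `writeCase` stores the full [HealingHistory-class] as `<path>` (RDS)
#' with a JSON sidecar `<path>.json`, atomically (temp file + rename).
#' `readCase` restores it, checking the schema version and that every day
#' group `day0 .. dayT` is present; the first missing day is named in the
#' error.
#'
#' @param history a [HealingHistory-class].
#' @param path file path (conventionally `*.rds`).
#' @return `writeCase` the path, invisibly; `readCase` the restored history.
#' @export
writeCase <- function(history, path) {
  stopifnot(is(history, "HealingHistory"))
  payload <- list(schema = .CASE_SCHEMA, history = history)
  tmp <- paste0(path, ".tmp")
  saveRDS(payload, tmp)
  file.rename(tmp, path)
  g <- gridSpec(history)
  meta <- list(schema = .CASE_SCHEMA, caseId = caseId(history),
               days = nDays(history) - 1L,
               grid = c(g@nrow, g@ncol), pixelSize = g@pixelSize,
               surrogate = isSurrogate(history),
               configHash = configHash(history@params))
  tmpj <- paste0(path, ".json.tmp")
  jsonlite::write_json(meta, tmpj, auto_unbox = TRUE, digits = NA)
  file.rename(tmpj, paste0(path, ".json"))
  invisible(path)
}

#' @rdname writeCase
#' @export
readCase <- function(path) {
  if (!file.exists(path)) stop("case file not found: ", path)
  payload <- readRDS(path)
  if (!identical(payload$schema, .CASE_SCHEMA))
    stop("case schema mismatch: expected ", .CASE_SCHEMA, ", found ",
         payload$schema %||% "<none>")
  h <- payload$history
  T <- length(h@days) - 1L
  for (t in 0:T) {
    key <- paste0("day", t)
    d <- h@days[[key]]
    if (is.null(d) || !all(c("material", "fields", "phenotype") %in%
                           names(d)))
      stop("case container is missing day group '", key, "'")
  }
  validObject(h)
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phenotype map export as plain-text PGM
#'
#' Writes the integer phenotype palette as an ASCII (P2) portable graymap,
#' the plain-text counterpart of a paletted image; `readPhenotypePGM`
#' restores it losslessly.
#'
#' @param map a [PhenotypeMap-class].
#' @param path output file.
#' @return the path (write) or the restored [PhenotypeMap-class] (read).
#' @export
writePhenotypePGM <- function(map, path) {
  m <- phenotypeMatrix(map)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2",
               paste("#", "MechanoHeal phenotype palette",
                     paste(sprintf("%s=%d", names(phenotypeCodes()),
                                   phenotypeCodes()), collapse = " ")),
               paste(ncol(m), nrow(m)),
               as.character(max(phenotypeCodes()))), con)
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname writePhenotypePGM
#' @export
readPhenotypePGM <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (ln[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  dims <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  vals <- as.integer(unlist(strsplit(trimws(ln[-(1:3)]), "\\s+")))
  m <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  PhenotypeMap(m)
}

#' JSON round trip for implant parameters and grid
#'
#' @param params an [ImplantParams-class]; `grid` a [GridSpec-class].
#' @param path JSON file path.
#' @param grid a [GridSpec-class].
#' @return the written path, or the restored object.
#' @name paramsJSON
NULL

#' @rdname paramsJSON
#' @export
writeImplantParams <- function(params, path, grid = NULL) {
  x <- list(bodyLength = params@bodyLength, bodyRadius = params@bodyRadius,
            threadPitch = params@threadPitch,
            threadDepth = params@threadDepth,
            threadProfile = params@threadProfile,
            apexShape = params@apexShape,
            collarHeight = params@collarHeight)
  if (!is.null(grid))
    x$grid <- list(nrow = grid@nrow, ncol = grid@ncol,
                   pixelSize = grid@pixelSize)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname paramsJSON
#' @export
readImplantParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- ImplantParams(bodyLength = x$bodyLength, bodyRadius = x$bodyRadius,
                     threadPitch = x$threadPitch,
                     threadDepth = x$threadDepth,
                     threadProfile = x$threadProfile,
                     apexShape = x$apexShape,
                     collarHeight = x$collarHeight)
  if (!is.null(x$grid))
    list(params = p, grid = GridSpec(x$grid$nrow, x$grid$ncol,
                                     x$grid$pixelSize))
  else p
}

#' Full run configuration
#'
#' The one validated settings object the command-line layer consumes.
#' Unknown keys are rejected.
#'
#' @param grid a [GridSpec-class].
#' @param healing a [healingConfig()].
#' @param surrogate a [surrogateConfig()].
#' @param nCases implant-library size.
#' @param seed master seed (fans out to library generation and training).
#' @param callusWidth,corticalThickness geometry settings.
#' @param outDir output directory.
#' @return validated config list with a `hash` field.
#' @export
runConfig <- function(grid = GridSpec(), healing = healingConfig(),
                      surrogate = surrogateConfig(), nCases = 65L,
                      seed = 1L, callusWidth = 3L,
                      corticalThickness = NULL, outDir = "cases") {
  cfg <- list(grid = list(nrow = grid@nrow, ncol = grid@ncol,
                          pixelSize = grid@pixelSize),
              healing = healing[setdiff(names(healing), "materials")],
              materials = healing$materials,
              surrogate = surrogate, nCases = as.integer(nCases),
              seed = as.integer(seed), callusWidth = as.integer(callusWidth),
              corticalThickness = corticalThickness, outDir = outDir)
  cfg$hash <- configHash(cfg[setdiff(names(cfg), "hash")])
  cfg
}

#' Validate a run-configuration list
#'
#' @param cfg list produced by [runConfig()] (possibly read back from JSON).
#' @return the config, invisibly; errors name unknown or missing keys.
#' @export
validateRunConfig <- function(cfg) {
  allowed <- c("grid", "healing", "materials", "surrogate", "nCases",
               "seed", "callusWidth", "corticalThickness", "outDir", "hash")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  need <- c("grid", "healing", "nCases", "seed")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("missing config keys: ",
                         paste(miss, collapse = ", "))
  invisible(cfg)
}

#' Deterministic toy fixtures for tests and examples
#'
#' Two tiny implant cases (32 x 16 grid) simulated for `days` days, with a
#' manifest of content hashes; repeated calls produce identical data.
#'
#' @param days simulated days (default 5).
#' @param seed RNG seed for the geometry draw (default 42).
#' @return list with `domains`, `histories` and `manifest` (named hash
#'   vector).
#' @export
makeFixtures <- function(days = 5L, seed = 42L) {
  grid <- GridSpec(32, 16, pixelSize = 0.3)
  doms <- generateImplantLibrary(2, seed = seed, grid = grid,
                                 callusWidth = 2L)
  cfg <- healingConfig(days = days)
  hs <- lapply(seq_along(doms), function(i)
    runHealing(doms[[i]], cfg, caseId = names(doms)[i]))
  names(hs) <- names(doms)
  manifest <- vapply(hs, function(h) {
    .fnv1a(paste(c(phenotypeMatrix(phenotypeDay(h, days)),
                   round(fieldsDay(h, days)@eps1, 12)), collapse = ","))
  }, character(1))
  list(domains = doms, histories = hs, manifest = manifest)
}
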