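.FORMAT_VERSION <- 1L

.as_chr <- function(x) if (length(x)) as.character(x) else character()
.as_int <- function(x) if (length(x)) as.integer(x) else integer()

.sketch_to_json <- function(sk) {
  obj <- if (is(sk, "MinHashSketch")) {
    list(format_version = .FORMAT_VERSION, algorithm = "minhash", k = sk@k,
         s = sk@s, seed = sk@seed, name = sk@name, n_kmers = sk@nKmers,
         hashes = sk@hashes)
  } else if (is(sk, "KssdSketch")) {
    list(format_version = .FORMAT_VERSION, algorithm = "kssd", k = sk@k,
         half_k = sk@halfK, drlevel = sk@drlevel, dict_seed = sk@dictSeed,
         dict_id = sk@dictId, name = sk@name, n_kmers = sk@nKmers,
         codes = sk@codes)
  } else if (is(sk, "OMHSketch")) {
    list(format_version = .FORMAT_VERSION, algorithm = "omh", k = sk@k,
         m = sk@m, l = sk@l, seed = sk@seed, name = sk@name,
         rows = lapply(sk@rows, function(r)
           list(hash = r$hash, kmer = r$kmer, occ = r$occ, pos = r$pos)))
  } else if (is(sk, "HLLSketch")) {
    list(format_version = .FORMAT_VERSION, algorithm = "hll", p = sk@p,
         k = sk@k, seed = sk@seed, name = sk@name,
         registers = base64_enc(as.raw(sk@registers)))
  } else {
    stop("not a sketch object: ", class(sk)[1])
  }
  # 64-bit values travel as decimal strings; numbers here are small/exact
  as.character(toJSON(obj, auto_unbox = TRUE, digits = NA))
}

.sketch_from_json <- function(line) {
  obj <- fromJSON(line, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(obj$algorithm) || is.null(obj$format_version))
    stop("not a genosketch sketch record (missing algorithm/format_version)")
  switch(as.character(obj$algorithm),
    minhash = new("MinHashSketch", k = as.integer(obj$k), s = as.integer(obj$s),
                  seed = as.numeric(obj$seed), name = .as_chr(obj$name),
                  nKmers = as.numeric(obj$n_kmers), hashes = .as_chr(obj$hashes)),
    kssd = new("KssdSketch", k = as.integer(obj$k),
               halfK = as.integer(obj$half_k), drlevel = as.integer(obj$drlevel),
               dictSeed = as.numeric(obj$dict_seed), dictId = .as_chr(obj$dict_id),
               name = .as_chr(obj$name), nKmers = as.numeric(obj$n_kmers),
               codes = .as_chr(obj$codes)),
    omh = new("OMHSketch", k = as.integer(obj$k), m = as.integer(obj$m),
              l = as.integer(obj$l), seed = as.numeric(obj$seed),
              name = .as_chr(obj$name),
              rows = lapply(obj$rows, function(r)
                data.frame(hash = .as_chr(r$hash), kmer = .as_chr(r$kmer),
                           occ = .as_int(r$occ), pos = .as_int(r$pos),
                           stringsAsFactors = FALSE))),
    hll = new("HLLSketch", p = as.integer(obj$p), k = as.integer(obj$k),
              seed = as.numeric(obj$seed), name = .as_chr(obj$name),
              registers = as.integer(base64_dec(obj$registers))),
    stop("unknown sketch algorithm '", obj$algorithm, "'"))
}

#' Read and write sketch files
#'
#' Sketches are stored as JSON lines: one JSON object per sketch with the
#' algorithm name, its parameters and its content. 64-bit hash values are
#' stored as decimal strings (never as JSON numbers) so no precision is lost
#' in any JSON reader; HyperLogLog registers are stored as base64. A
#' write/read round trip reproduces every sketch bit-exactly.
#'
#' @param x a sketch object or a list of sketch objects.
#' @param path file path.
#' @return \code{writeSketches} returns \code{path} invisibly;
#'   \code{readSketches} returns a list of sketch objects (possibly empty for
#'   an empty file).
#' @examples
#' sk <- minhashSketch(randomGenome(500, seed = 1), k = 11, s = 50)
#' f <- tempfile(fileext = ".gsk")
#' writeSketches(sk, f)
#' identical(readSketches(f)[[1]], sk)
#' @export
writeSketches <- function(x, path) {
  if (is(x, "MinHashSketch") || is(x, "KssdSketch") || is(x, "OMHSketch") ||
      is(x, "HLLSketch")) x <- list(x)
  stopifnot(is.list(x))
  writeLines(vapply(x, .sketch_to_json, character(1)), path)
  invisible(path)
}

#' @rdname writeSketches
#' @export
readSketches <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    sk <- tryCatch(.sketch_from_json(l),
                   error = function(e) stop("cannot parse sketch file '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
    validObject(sk)
    sk
  })
}

#' Read and write Kssd dictionary files
#'
#' The full shuffled permutation is stored as JSON together with its
#' parameters; on reading, the permutation is validated and the dictionary id
#' recomputed, so a corrupted file cannot silently change which k-mers are
#' sampled.
#'
#' @param dict a \linkS4class{KssdDictionary}.
#' @param path file path.
#' @return \code{readKssdDictionary} returns the \linkS4class{KssdDictionary}.
#' @export
writeKssdDictionary <- function(dict, path) {
  stopifnot(is(dict, "KssdDictionary"))
  obj <- list(format_version = .FORMAT_VERSION, type = "kssd_dictionary",
              half_k = dict@halfK, drlevel = dict@drlevel, seed = dict@seed,
              perm = dict@perm)
  writeLines(as.character(toJSON(obj, auto_unbox = TRUE, digits = NA)), path)
  invisible(path)
}

#' @rdname writeKssdDictionary
#' @export
readKssdDictionary <- function(path) {
  obj <- fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$type, "kssd_dictionary"))
    stop("'", path, "' is not a Kssd dictionary file")
  perm <- as.integer(obj$perm)
  id <- sprintf("kssd:L%d:d%d:seed%s:%s", as.integer(obj$half_k),
                as.integer(obj$drlevel), format(as.numeric(obj$seed)),
                cpp_perm_checksum(perm))
  d <- new("KssdDictionary", halfK = as.integer(obj$half_k),
           drlevel = as.integer(obj$drlevel), seed = as.numeric(obj$seed),
           perm = perm, dictId = id)
  validObject(d)
  d
}
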