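# Small internal helpers shared across modules.

# 32-bit FNV-1a over the UTF-8 bytes of `x`, done in doubles (R has no
# unsigned 32-bit integer).  Multiplication is split 16/16 so intermediate
# products stay below 2^53.
fnv1a32 <- function(x, basis = 2166136261) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- basis
  for (b in bytes) {
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- bitwXor(as.integer(lo), bitwAnd(as.integer(b), 255L)) +
      hi * 65536
    # h * 16777619 mod 2^32
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  h
}

hash_hex <- function(x) {
  hex8 <- function(h) {
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
  }
  paste0(hex8(fnv1a32(x)), hex8(fnv1a32(x, basis = 40389)))
}

# Last path/fragment segment of an IRI.
iri_fragment <- function(iri) {
  frag <- sub(".*[#/]", "", iri)
  if (!nzchar(frag)) iri else frag
}

# "MyocardialInfarction" / "has_part" -> "myocardial infarction" / "has part"
humanize_fragment <- function(fragment) {
  s <- gsub("[_-]+", " ", fragment)
  s <- gsub("(?<=[a-z0-9])(?=[A-Z])", " ", s, perl = TRUE)
  s <- gsub("(?<=[A-Z])(?=[A-Z][a-z])", " ", s, perl = TRUE)
  s <- tolower(s)
  trimws(gsub("[[:space:]]+", " ", s))
}

# Indefinite article by initial letter; no pluralization.
article_for <- function(noun) {
  if (!nzchar(noun)) return("a")
  if (grepl("^[aeiou]", noun, ignore.case = TRUE)) "an" else "a"
}

is_blank_node <- function(x) is.character(x) && startsWith(x, "_:")

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_ontoqc <- function(message, class) {
  stop(structure(
    class = c(class, "ontoqc_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

warn_ontoqc <- function(message, class) {
  warning(structure(
    class = c(class, "ontoqc_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}
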