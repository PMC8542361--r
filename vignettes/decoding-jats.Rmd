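---
title: "Decoding NISO-JATS articles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding NISO-JATS articles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jatsr)
```

## The problem

NISO-JATS is the NISO standard XML vocabulary for journal articles and the
archival format of PubMed Central (PMC), whose open-access collection holds
millions of NXML files. The tag set is well documented but was not designed
to aid text mining: the same information appears at different levels, in
different elements, and in different character encodings depending on the
publisher and the vintage of the file. Anyone who wants to compute over
that corpus — tag-use statistics, publication-history lags, country
networks, full-text search — first needs a decoder that tolerates the
dialects actually found in the wild.

`jatsr` is that decoder. It extracts a unified record per article (title,
journal, DOI, type, volume, subjects, keywords, contributors with
identifiers, affiliations, countries, history date stamps, abstract,
sectioned text, references), profiles whole collections into bibliometric
tables, and ships a fixture forge that generates synthetic JATS files with
exact ground truth so that every extractor is testable offline, without a
corpus download.

## Reading and fragment extraction

Files are read honouring the encoding declared in the XML prolog, falling
back to UTF-8 and then to Latin-1 (in which every byte sequence is valid),
logging any fallback. DOCTYPE declarations are kept verbatim and never
fetched.

Extraction deliberately does **not** require well-formed XML. A archive
spanning centuries of scanned and re-keyed material contains files no
strict parser accepts, and one bad element must not cost the whole record.
`extract_fragments()` therefore scans for balanced open/close tags of the
requested element name, ignoring namespace prefixes, and returns every
top-level occurrence in document order. In the test suite a strict parser
(xml2) serves as the oracle on repaired documents: both routes must agree.

## Character unification

PMC codes special characters as hexadecimal (`&#x3B1;`), decimal
(`&#945;`) or named (`&alpha;`) entities, uses many distinct Unicode
spaces and dashes, and renders the same letter in bold, italic or script
math variants. `convert_letters()` maps all of that to one canonical form:

* numeric entities of both bases decode to their code point; the named
  table covers the XML predefined set, the full Latin-1 supplement, Greek,
  and roughly a hundred common punctuation/math names (about 250 names in
  `inst/extdata/entities.tsv`). Unknown or malformed entities are left
  verbatim and logged rather than guessed at.
* 21 space codings (tab, no-break, en/em/thin/hair, ideographic, zero
  width, BOM, ...) unify to a plain space; 11 hyphen/dash variants unify
  to `-`. Both tables ship as plain-text files.
* styled character variants fold to plain equivalents: the
  math-alphanumeric block (13 Latin styles, Greek runs, digit runs),
  fullwidth forms and ligatures. This map is arithmetic by construction
  and is computed at load time rather than shipped.
* hyperlinks and HTML formatting tags (`<italic>`, `<sup>`, ...) are
  removed, keeping their content; runs of spaces collapse; output is
  NFC-normalised.

The pipeline runs to a fixpoint (at most six passes), which makes it
idempotent by construction and resolves double-encoded entities such as
`&amp;#x3b1;`. Idempotence is enforced by a property test over generated
strings.

Spacing corrections are under-specified in the wild, so the rule set is
fixed and documented:

| rule | example |
|---|---|
| whitespace runs collapse to one space | `a  b` → `a b` |
| no space before `, . ; : ? ! ) ] %` (decimal points kept) | `cases , roughly .` → `cases, roughly.` |
| no space after `(` `[` | `( p` → `(p` |
| spaces around `=` removed | `p = .05` → `p=.05` |
| space restored after sentence punctuation between lower and upper case | `end.Next` → `end. Next` |

## Formula flattening

MathML and MathJax/LaTeX formulas flatten to plain text in reading order:
tags are dropped, entities decoded, styled variants folded, LaTeX
delimiters stripped, and a fixed macro table applied (greek letters,
`\frac{a}{b}` → `a/b`, comparison operators to `<=`-style keyboard forms,
sub/superscripts to their bare arguments). Anything outside the table
degrades to its concatenated arguments — the goal is searchable text, not
typesetting. A formula represented only by a hyper-referenced pixel image
carries no text at all: it yields an empty string, an `image_formula`
flag, and a log entry, so that downstream counts can report how much
content is locked in images.

## Publication history

Histories use 14 observed stamp labels (`accepted`, `collection`,
`ecorrected`, `epreprint`, `epub`, `nihms_submitted`, `pmc-release`,
`ppub`, `print`, `pub`, `received`, `retracted`, `rev-recd`,
`submitted`); unknown labels land in a logged catch-all. Stamps without a
numeric year are dropped; a duplicated label keeps its first occurrence.
Month and day stay `NA` as extracted and are completed to 1 only at
comparison time.

The unified publication date is the earliest completed date over the six
publication-event stamps `{epub, ppub, print, pub, collection,
pmc-release}` — the remaining eight labels denote editorial or
administrative events, not publication. When none of the six is present
the publication year falls back to the earliest year over all stamps.
Note one consequence of the completion rule: a year-only `collection`
stamp completes to January 1 and can precede a later, fully dated `epub`;
the rule is applied uniformly and this bias is accepted and documented
rather than special-cased.

Editorial lags are plain day differences: time to accept = accept −
receive, time to publish = publication date − accept. Negative values are
preserved deliberately — they are the anomaly signal the profiler counts.
Future-dated stamps (e.g. a year 2100 accept date) are likewise retained
and flagged by the profiler against an explicit reference date, never
against the wall clock.

## Contributors, affiliations, countries

All-caps name parts (a common journal style) are recased to an initial
capital per token, Unicode-aware; mixed-case input is never touched, so
"McDonald" and particles like "van" survive. Given names optionally
shorten to one-letter abbreviations. Contributor identifiers are read
from `contrib-id` elements with scheme detection; a bare 16-digit ORCID
form is recognised when the type attribute is missing.

Affiliations are reduced to one comma-separated string per `<aff>`
element (tags removed, label markers stripped). Country recognition
prefers an explicit `<country>` tag; otherwise a dictionary search
anchored at the *end* of the affiliation string is performed, after
stripping trailing postal codes and e-mail addresses. The dictionary
(about 200 canonical names plus an alias file with forms like "Peoples
Rep. of China", "UNITED STATES", "UK") ships as data, not code. End
anchoring is what keeps "Georgia Institute of Technology, Atlanta" from
matching a country; the flip side — an affiliation that mentions its
country mid-string only — is accepted as a miss and logged nowhere, since
there is no reliable signal.

## Text parts

Sections and subsections are not differentiated: the body flattens to one
ordered list of `{title, text}`, parents before children, untitled
leading material kept with an empty title. Figures, tables and their
captions are excluded from section text; formulas pass through the
flattener. The presence rule is uniform: an abstract or body text under
30 characters counts as not present.

`split_into_main_sections()` merges that flat list into main sections: a
title containing any pattern (case-insensitive substring) opens a group
and absorbs every following non-matching section; material before the
first match forms its own leading group, so text is conserved — the
concatenation of group texts equals the concatenation of inputs, an
invariant tested against an independent brute-force reference.

`text2sentences()` splits at `. ! ?` followed by whitespace and an
uppercase letter or digit. Protected positions: decimal numbers, a
shipped abbreviation list (`e.g.`, `et al.`, `Fig.`, `vs.`, `approx.`,
...), initial chains ("J. R. Smith") and leading ordinal enumerators. A
*lone* capital letter before a period is treated as sentence-final
("... group A. Group B ..." splits) — the cost is that a standalone
initial directly before a surname can over-split; abbreviations missing
from the list over-split too. Both limitations are accepted: the
splitter is regex-based by design, and joining the sentences with single
spaces always reconstructs the input up to whitespace.

## Corpus profiling

`decode_collection()` returns a tibble, one row per decodable file, list
columns for the multi-valued fields; failures are logged and skipped.
The profiler computes:

* `tag_use_table()` — presence frequency per content element, overall and
  per publishing period. Bins are right-closed, the first bin closed on
  both sides; records without a publication year count in the total
  column but in no period column (so period totals need not sum to the
  corpus total).
* `frequency_table()` — label counts for type/journal/date
  label/name/subject/keyword/country, with journal productivity bins at
  edges 1, 2–10, 11–100, 101–1000, 1001–10^4, 10^4–10^5, >10^5.
* `date_anomalies()` — counts of accept-before-receive,
  publish-before-accept, and future-dated records.
* `country_cooccurrence()` — unordered country-pair counts and the
  international share (fraction of country-bearing records with more than
  one country).

All tables are written as CSV with stable column order by
`write_profile()`; thin CLI wrappers live in `inst/cli/`.

## The fixture forge

`generate_article()` builds a JATS file from a seeded draw of realistic
content pools and returns, alongside the XML, the exact record its decode
must produce. Quirks are orthogonal toggles over the surface encoding —
entity styles, all-caps names, alternative space codings, untagged
affiliations, nested subject groups, MathML or image-only formulas,
duplicate date labels, year-only stamps, subsectioned bodies — and are
semantics-preserving: the ground truth of a fixture is identical with and
without any surface quirk. Three quirks plant date anomalies
(`reversed_accept_receive`, `publish_before_accept`, `future_date`) and
set the corresponding truth flags; `publish_before_accept` exists so the
profiler's second anomaly counter has a planted signal of its own.

`generate_corpus()` realises feature prevalences by deterministic
allocation — exactly `round(n × p)` records carry each feature, spread by
a rotating offset — rather than sampling, so profiler tests compare exact
counts with no flakiness. Defaults resemble a recent open-access corpus:
abstracts and body text at 0.9, keywords 0.6, editors 0.15, about 30% of
country-bearing records international, and a small planted handful of
date anomalies.

What the forge does **not** emulate: the full breadth of real tag soup
(publisher-specific extensions, deeply broken markup beyond single
unclosed elements), non-Latin scripts in names and text, multi-article
files, PDF-converter artifacts, or the skewed long-tail distributions of
real journals and authors. Green tests therefore demonstrate that the
extraction rules are implemented exactly as specified and are stable
under the encoded dialect variation — not that every real PMC file
decodes perfectly.

## Problem sizes and numerical choices

The test suite checks the round trip on 200 fixtures spanning every quirk
(singly and in random combinations), conversion idempotence on 1,000
generated strings, section-merge conservation on 100 random section lists
against the brute-force reference, a 53-sentence hand-segmented oracle,
and profiler conservation on a 1,000-article forged corpus — sizes chosen
so the whole suite runs in a couple of minutes on one CPU. Dates are
compared on completed `Date` values; table frequencies are rounded to 4
decimals for stable CSV diffs; ties in frequency tables break
alphabetically.

## Known limitations

* Named-entity coverage is the common subset described above, not the
  full HTML5 list; unknown names are preserved verbatim and logged.
* The country alias list is curated, not exhaustive; ambiguous tokens
  ("Georgia") resolve by position only.
* Sentence segmentation is heuristic; see the protections above.
* Records are decoded independently; no cross-document author
  disambiguation is attempted (name siblings such as the many "Wang,
  Wei"s stay merged).
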