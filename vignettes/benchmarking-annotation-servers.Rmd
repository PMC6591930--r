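---
title: "Benchmarking annotation servers: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking annotation servers: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annobench)
```

## The problem

Biomedical named-entity annotation servers are web services: given document
identifiers, they fetch the raw text and return stand-off entity
predictions. Integrating such services into text-mining workflows raises
questions that quality benchmarks do not answer — does the server keep
responding under bursty load, how fast, with how many predictions per
document, and does it honour the rules of continuous evaluation (no
document caching, no prediction caching)? `annobench` is a self-contained
harness for exactly this *technical* evaluation: it plays the role of the
metaserver (scheduling requests, collecting responses, logging events) and
of the document providers, and either simulates the annotation servers
through configurable behaviour profiles or drives real HTTP endpoints.
Annotation quality (precision/recall/F) is deliberately out of scope.

## The stand-off annotation model and formats

Every prediction is eight fields: document id, section, `init` (0-based
character start), `length` (≥ 1 characters), `end = init + length`
(half-open), a confidence score in [0, 1], the surface text, the entity
type, and an optional database identifier. Offsets are **character**
positions, not bytes, counted over the document's full text.

Two conventions had to be fixed because interchange practice varies:

* **Document concatenation.** A document's text is its units (title,
  abstract) joined in offset order by a single newline; the title sits at
  offset 0 and the abstract at `nchar(title) + 1`. One fixed, documented
  convention is required for offset validation to be meaningful.
* **Half-open spans.** The TSV's "end" column is `init + length`, matching
  the BioC offset+length convention; the worked-example arithmetic
  (an annotation at init 103 with length 13 ends at 116) confirms it.

Three formats share this model: a BioC XML subset (collection → document →
passage → annotation, section as a passage infon, one location per
annotation; relations and sentence nodes on input are ignored), a
field-for-field BioC JSON mirror, and a headerless 8-column TSV (empty
string for a missing database id, scores printed to ≤ 6 significant
digits). Readers accept LF and CRLF; writers emit LF/UTF-8. The XML subset
is declared as an XSD shipped with the package, and serialization
validates against it in the test suite. Parsing is *total*: malformed
records raise errors naming the offending line or element rather than
being dropped, so a payload's annotation count always equals the parsed
count.

Validation against documents flags out-of-bounds spans, surface-text
mismatches (compared case-insensitively but whitespace-exactly, so a
predicted term can be located "with independence of text case"),
unresolvable document ids, and — only when a vocabulary is supplied —
unknown entity types. The vocabulary is open by default: the twelve
reference types ship with the package, but servers may propose their own.

The shipped worked-example payload stores the printed location values
(offset 103, length 13) for a surface string of 11 characters; the
mismatch is kept verbatim and documented in the fixture, and doubles as a
validation test case.

## Server registry

Registries are human-editable YAML. Metadata is tiered: mandatory fields
(name, institution, administrator contact, main programming language,
non-empty supported types and formats, software version) are validated on
load — a missing one is a registration error naming server and field —
while recommended (license, third-party components, dedicated server,
references) and optional (OS, hardware, distributed processing) fields
only affect the reported completeness tier. Unknown keys are preserved,
not rejected. Entity-type labels are normalized case-insensitively onto
canonical names before any counting, since harmonizing heterogeneous
server vocabularies is the point of a metaserver.

The shipped registry fixture transcribes the 15 servers of the published
first campaign. Its per-server entity-type sets are a *reconstruction*:
the published support matrix is only machine-recoverable through its
marginals (how many servers per type, how many types per server), so the
fixture holds a 0/1 matrix computed to match both marginal vectors
exactly, with a few plausibility constraints (the single-type servers get
their namesake type; the widest server carries the sole Gene Ontology
support). Every coverage statistic the package asserts — 12 distinct
types, chemical supported by 10 servers and disease by 9, a maximum of 10
types on one server, and 12·11/2 = 66 theoretically extractable pairwise
co-occurrence relation types — depends only on the marginals and is
therefore exact. The printed table also carries no software version
column, so the fixture sets a placeholder version for every record.

## Synthetic corpora

The generator emulates the three content providers with a per-provider
profile:

| parameter | patent | abstract/pubmed | rationale |
|---|---|---|---|
| `mean_length` | 582 chars | 1326 chars | the published provider averages |
| `length_dispersion` | 30% of mean | 30% of mean | only means are published; a 30% spread is a realistic document-length variation, and the calibration check depends only on the mean |
| floor | 50 chars | 50 chars | degenerate documents are unrealistic and break title/abstract layout |
| `mention_density` | 4 / doc | 9 / doc | roughly one mention per 140 characters, in line with observed annotations-per-document medians around 10 |
| `type_mix` | uniform over 12 types | uniform | no published per-type frequencies |
| `compliance_fraction` | 0.1 | 0.1 | enough perturbed documents for cache verdicts at desk scale |

Documents are word-shaped random filler tokens with real mentions injected
from a shipped mini-lexicon (≥ 6 surface forms per type), so the corpus
needs no downloads and every mention's offsets are known exactly — the
ground truth always validates against the text, a property the suite
checks for original and perturbed versions alike. Per-document target
lengths are drawn from the truncated normal and then hit *exactly* by the
token assembler, so the sample mean converges to the profile mean at the
usual `dispersion/√n` rate; the calibration tests use n = 10,000 and a
3-standard-error band.

What the generator does **not** emulate: natural-language syntax, realistic
term frequency distributions, section structure beyond title/abstract, or
ambiguous/overlapping mentions. Passing tests therefore demonstrate
correct *bookkeeping* (offsets, formats, metrics, caching logic) under
controlled conditions, not NER difficulty on real text.

**Compliance documents.** A compliance document's first serve returns the
original (version 1); every further serve regenerates the document from a
seed derived from (document seed, version): all filler is reworded (far
beyond the ≥ 10% design minimum) and at least one embedded mention is
forced to differ from the original, so an honest tagger's annotation sets
necessarily differ between versions. Compliance documents are generated
with at least one mention for the same reason — a mention-free compliance
document carries no signal. Perturbation is deterministic given (seed,
version), so benchmark runs replay exactly.

## Request plans and the harness

Windows expand deterministically: regular windows place requests at the
end of each of n equal subintervals; irregular windows draw issue times
uniformly within the window from the plan seed (the emulation of bursty
load); `mix` windows sample a concrete provider per request. Windows of
the same provider and kind may not overlap. The shipped `tips2017`
template reproduces the published 14-cell two-month schedule — 318,629
requests over a 53-day (4,579,200 s) window — and `scale` shrinks every
cell proportionally with rounding.

The harness records exactly one event per (request × server):
conservation, `|log| = requests × servers`, is an invariant of the run
loop, not an observed property. Each request serves its batch documents
once from the provider corpus (advancing compliance versions) and hands
the same served versions to every server, mirroring a metaserver relaying
one scheduled request to all registered services. The simulated clock is
event-driven — issue times come from the plan, delays from the latency
model — so a 1%-scaled campaign (≈ 3,187 requests × 15 servers ≈ 47,800
events) replays in well under a minute.

**Failure definition.** A request counts as a failure if no complete,
parseable response arrives before the deadline: scripted failure windows
and over-deadline latency draws surface as `timeout`, transport errors as
`error`, and unparseable payloads as `malformed`. The default deadline is
60 s per request; it is configurable and carried by the plan. Batch
requests yield one response regardless of batch size, with document bytes
and annotation counts summed over the batch — the metric denominators
count responses, not documents.

Honest profiles are dictionary taggers over the corpus lexicon: they
annotate exactly the embedded mentions of their supported types in the
*served* version, which makes their payloads valid by construction and
their behaviour the reference for cache detection. A `caches_predictions`
profile replays the payload recorded at first sight of each document id —
the forbidden behaviour the detector must catch.

## Metrics: numerical choices

Downtime intervals are maximal runs of consecutive failed requests: an
interval starts at the issue time of the run's first failed request and
ends at the issue time of the first subsequent ok response (window end if
none). Performance sums (ART, MAD, MTSA, MTDV) run over ok responses only;
this matches the published treatment, where a server whose every response
was empty still has a defined ART while its predictions are zero.

* **MTBF** is read as mean uptime per failure, with uptime resuming at the
  end of each downtime interval and the first span starting at the window
  start; with zero failures it equals the full window length and MTTR is 0.
  Total uptime plus total downtime equals the window length exactly
  (property-tested).
* **MTSA with zero predictions** is a typed undefined sentinel (`NA`),
  never 0 or infinity, and is excluded from medians.
* **MTDV units** are seconds per byte (Σ time / Σ size). The original
  summary table labels the metric "(B/s)", but the defining equation and
  the magnitudes of the published per-server values (~10⁻³ for ~1 s
  responses over ~1 kB documents) both give s/B; the package follows the
  equation and documents the deviation from the unit label.
* **Medians** are middle-of-sorted (mean of the two middle values for even
  counts), computed over servers with defined values; the MAD median is
  additionally reported rounded to the nearest integer. Report exports
  print in 3-significant-figure scientific notation for comparability with
  the published results table. On that table the package reproduces median
  ART 3.74 s and a rounded MAD median of 10.
* One published inconsistency is kept as printed: the narrative gives the
  fastest repair as 5.8 h while the results table's value equals 5.89 h;
  the fixture stores the table value.

**Cache detection.** For every compliance document with at least two ok
responses at different served versions, the annotation sets (type, init,
length, text) are compared: all-identical across every usable document
flags the server; any difference clears it; fewer than two usable
responses for every compliance document is insufficient evidence. The
corpus perturbation guarantee makes the detector sound for honest taggers
that support at least one embedded type — the suite checks zero false
positives over 50 seeded trials. A known limitation, inherent to the
criterion: a server that honestly returns *no* annotations for every
compliance document is indistinguishable from a cache replaying empty
payloads, and is flagged.

## Determinism and problem sizes

All randomness flows from explicit integer seeds through a 31-bit
derivation chain (document seeds, perturbation streams, plan expansion and
response draws are independent streams), so corpora are byte-identical
under a repeated seed and whole benchmark runs replay exactly. The test
suite exercises the properties at sizes chosen to keep a full run at desk
scale: ≥ 100 random payloads for format round-trips, 20 random logs for
the metric identities, n = 1000 for exponential-latency mean recovery
(3-standard-error band), 50 seeded cache-detection trials, n = 10,000
documents per provider for length calibration, and a 1%-scale campaign
replay against the full 15-server fleet.

## Known limitations

* Simulated servers are dictionary taggers over generated text; nothing is
  claimed about real NER behaviour or annotation quality.
* The HTTP transport is implemented behind the same contract as the
  simulator but requires a live endpoint, so it is not exercised by the
  test suite.
* Latency models are stationary per server; real services drift with load
  and time of day. Load-dependent latency can be approximated by splitting
  a campaign into windows and assigning profiles per window.
* Only title/abstract document structure is modelled; no full-text
  sections, no relation annotations, no visualization.
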