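# annobench

Continuous technical benchmarking of biomedical annotation servers.

Online named-entity annotation servers (AS) — web services that fetch a
document on request and return stand-off entity predictions — are usually
compared on annotation *quality* (precision/recall/F). `annobench` addresses
the complementary question that matters once such a service is wired into a
production text-mining workflow: **is the server fast, stable and
format-compliant under sustained, bursty load?** It provides a
metaserver-style harness that any group can run on a desk machine, with no
external services or downloads:

* **Synthetic document providers.** Seeded generators emulating patent
  (mean 582 characters) and abstract/PubMed-style (mean 1326 characters)
  content sources. Documents are filler text with real biomedical entity
  mentions injected from a shipped lexicon at known offsets, giving every
  document exact ground truth. A configurable fraction are *compliance
  documents*, perturbed between serves so that prediction caching (which is
  forbidden) becomes detectable.
* **Three interchange formats** over one stand-off model — BioC XML (with a
  shipped XSD), BioC JSON, and an 8-column offset TSV — with parsing,
  writing, lossless interconversion and offset/text/type validation.
* **A load scheduler** expanding regular (evenly spaced) and irregular
  (burst) request windows into deterministic request plans; the shipped
  `tips2017` template reproduces a published two-month campaign schedule
  (318,629 requests over a 53-day window) and scales down proportionally.
* **Simulated server fleets** with per-server latency models, scripted
  failure windows, malformed-response rates and (optionally) the
  caching cheat; real HTTP endpoints can be plugged in behind the same
  transport contract.
* **Six evaluation metrics** derived from the event log, per server and per
  provider, with median summaries, leaderboards and cache verdicts.

## The metrics

With sums over *ok* responses only (R responses, P total predictions,
response times t, requested document bytes b), and downtime intervals
derived from maximal runs of failed requests:

| metric | definition | meaning |
|---|---|---|
| ART | Σt / R | average response time (s) |
| MAD | P / R | mean annotations per document |
| MTSA | Σt / P | mean time to seek an annotation (s); undefined when P = 0 |
| MTDV | Σt / Σb | mean time per document volume (s/byte) |
| MTTR | Σ downtime / failures | mean time to repair (s) |
| MTBF | Σ uptime / failures | mean time between failures (s) |

A *failure* is any request without a complete parseable response before the
deadline (timeout, transport error, or malformed payload). The identities
`MTSA × MAD = ART` and `MTDV × (mean bytes/response) = ART` hold exactly and
are property-tested.

## Worked example

```r
library(annobench)

# a small benchmark: 1 honest server, 1 server with scripted downtime
corpus <- generate_corpus(provider_profile("patent"), 30, seed = 5)
plan   <- build_plan(plan_window(0, 1000, "regular", "patent", 100),
                     seed = 2, deadline = 5)
fleet  <- list(
  behavior_profile(1, latency = list(family = "constant", value = 1.0)),
  behavior_profile(2, latency = list(family = "constant", value = 0.5),
                   failure_windows = data.frame(start = 95, end = 195)))

log    <- run_benchmark(plan, fleet, corpus)
compute_metrics(log)
#>   server_id requests responses predictions failures ART   MAD  MTSA     MTDV MTBF MTTR
#> 1         1      100       100         434        0 1.0  4.34 0.230 0.00178  1000    0
#> 2         2      100        90         398        1 0.5  4.42 0.113 0.00089   900  100
```

Server 2's ten requests issued inside its failure window (95–195 s) form one
downtime interval [100, 200): it repaired once (MTTR = 100 s) and was up for
the remaining 900 s (MTBF = 900 s). Its 90 ok responses average 0.5 s (ART)
with ~4.4 annotations per document (MAD).

The published campaign fixtures reproduce the printed summaries:

```r
coverage_summary(load_fixture("registry"))   # 12 types, 66 pairwise relations
median_summary(load_fixture("results"))      # median ART 3.74 s, MAD ~ 10
leaderboard(load_fixture("results"))         # server 122 leads at 1.07 s
```

A thin command-line wrapper ships at `inst/cli/annobench`
(`generate`, `run`, `score`, `fixtures` subcommands).

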