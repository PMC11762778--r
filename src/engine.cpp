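// Event-driven core of the senescence simulator.
//
// Cell state: type (1 = A, 2 = B), cycle type (1 = nor, 2 = nta, 3 = sen),
// telomere lengths as 32 ints (2 ends x 16 chromosomes).  All randomness
// goes through R's generator (unif_rand), so runs are reproducible from
// set.seed() on the R side.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Params {
  double a_nta, b_nta, a_sen_A, b_sen_A, a_sen_B, b_sen_B;
  double l_min_A, l_min_B, p_accident, p_repair, p_death, h, D;
};

static Params read_params(const List& p) {
  Params P;
  P.a_nta = p["a_nta"]; P.b_nta = p["b_nta"];
  P.a_sen_A = p["a_sen_A"]; P.b_sen_A = p["b_sen_A"];
  P.a_sen_B = p["a_sen_B"]; P.b_sen_B = p["b_sen_B"];
  P.l_min_A = p["l_min_A"]; P.l_min_B = p["l_min_B"];
  P.p_accident = p["p_accident"]; P.p_repair = p["p_repair"];
  P.p_death = p["p_death"]; P.h = p["h"]; P.D = p["D"];
  return P;
}

// p(l) = min(1, b exp(-a l)) above the threshold, 1 at or below it
static inline double arrest_law(double a, double b, double lmin, double l) {
  if (l <= lmin) return 1.0;
  double v = b * std::exp(-a * l);
  return v > 1.0 ? 1.0 : v;
}

struct Fate {
  bool alive;
  int type, cyc;   // daughter's type and cycle type
  bool onset;      // this division started a terminal senescent sequence
  int cause;       // 0 none, 1 senescence, 2 accident
};

// Onset checks for a daughter in the normal-cycling regime (either its
// mother cycled normally, or it just exited an nta sequence via repair).
static inline Fate onset_checks(int type, double l, const Params& P) {
  Fate f; f.alive = true; f.onset = false; f.cause = 0;
  if (type == 1) {
    if (unif_rand() < arrest_law(P.a_sen_A, P.b_sen_A, P.l_min_A, l)) {
      f.type = 1; f.cyc = 3; f.onset = true; return f;
    }
    if (unif_rand() < arrest_law(P.a_nta, P.b_nta, -1e308, l)) {
      f.type = 2; f.cyc = 2; return f;   // first nta: the type switches to B
    }
    f.type = 1; f.cyc = 1; return f;
  }
  if (unif_rand() < arrest_law(P.a_sen_B, P.b_sen_B, P.l_min_B, l)) {
    f.type = 2; f.cyc = 3; f.onset = true; return f;
  }
  if (unif_rand() < arrest_law(P.a_nta, P.b_nta, -1e308, l)) {
    f.type = 2; f.cyc = 2; return f;
  }
  f.type = 2; f.cyc = 1; return f;
}

// Per-daughter transition kernel; mirrors next_cell_fate() on the R side.
static inline Fate next_fate(int mtype, int mcyc, double l, const Params& P) {
  Fate f;
  if (unif_rand() < P.p_accident) {
    f.alive = false; f.type = mtype; f.cyc = mcyc; f.onset = false; f.cause = 2;
    return f;
  }
  if (mcyc == 3) {                         // senescence is absorbing
    if (unif_rand() < P.p_death) {
      f.alive = false; f.type = mtype; f.cyc = 3; f.onset = false; f.cause = 1;
      return f;
    }
    f.alive = true; f.type = mtype; f.cyc = 3; f.onset = false; f.cause = 0;
    return f;
  }
  if (mcyc == 2) {                         // nta sequence: repair/adapt or stay
    if (unif_rand() < P.p_repair) return onset_checks(2, l, P);
    f.alive = true; f.type = 2; f.cyc = 2; f.onset = false; f.cause = 0;
    return f;
  }
  return onset_checks(mtype, l, P);
}

static inline double draw_duration(const NumericVector& pool) {
  int n = pool.size();
  int i = (int)(unif_rand() * n);
  if (i >= n) i = n - 1;
  return pool[i];
}

static inline const NumericVector& pool_for(int type, int cyc,
                                            const NumericVector& norA,
                                            const NumericVector& norB,
                                            const NumericVector& nta,
                                            const NumericVector& sen) {
  if (cyc == 2) return nta;
  if (cyc == 3) return sen;
  return type == 1 ? norA : norB;
}

// Simulate one 24-h culture window of the population experiment.
// Cells divide at birth_time + tau; both daughters are kept; division
// events stop once the living count reaches n_sat ("frozen" until the
// dilution, handled on the R side).  Returns the end-of-window state,
// the senescence-onset log and hourly living counts.
// [[Rcpp::export]]
List cpp_run_day(IntegerMatrix telo, IntegerVector type, IntegerVector cyc,
                 IntegerVector gen, IntegerVector anc, NumericVector div_time,
                 double t_start, double t_end, int n_sat,
                 List params, List bank) {
  const Params P = read_params(params);
  const NumericVector norA = bank["nor_A"], norB = bank["nor_B"],
                      ntaD = bank["nta"], senD = bank["sen"];
  const int n0 = type.size();
  if (telo.nrow() != 32 || telo.ncol() != n0)
    stop("cpp_run_day: telo must be 32 x n");

  std::vector<int> teloV; teloV.reserve((size_t)32 * (n0 + 1024));
  std::vector<int> typeV, cycV, genV, ancV;
  std::vector<double> timeV;
  std::vector<char> aliveV;
  std::vector<int> freeSlots;

  for (int i = 0; i < n0; ++i) {
    for (int j = 0; j < 32; ++j) teloV.push_back(telo(j, i));
    typeV.push_back(type[i]); cycV.push_back(cyc[i]);
    genV.push_back(gen[i]); ancV.push_back(anc[i]);
    timeV.push_back(div_time[i]); aliveV.push_back(1);
  }

  typedef std::pair<double, int> Ev;
  std::priority_queue<Ev, std::vector<Ev>, std::greater<Ev> > heap;
  for (int i = 0; i < n0; ++i) heap.push(Ev(timeV[i], i));

  std::vector<double> onset_t, onset_l;
  std::vector<int> onset_ty;
  std::vector<double> hour_t;
  std::vector<int> hour_n;
  double next_mark = std::floor(t_start / 60.0) * 60.0 + 60.0;

  int alive_count = n0;
  bool frozen = false;
  double t_freeze = t_end;
  long n_div = 0;

  int Lbuf[32], d1[32], d2[32];

  while (!heap.empty()) {
    double t = heap.top().first;
    int s = heap.top().second;
    if (t > t_end) break;
    heap.pop();

    while (next_mark <= t) {
      hour_t.push_back(next_mark); hour_n.push_back(alive_count);
      next_mark += 60.0;
    }

    // mother state
    const int mT = typeV[s], mC = cycV[s], mG = genV[s], mA = ancV[s];
    for (int j = 0; j < 32; ++j) Lbuf[j] = teloV[(size_t)32 * s + j];
    aliveV[s] = 0; freeSlots.push_back(s);
    --alive_count;
    ++n_div;

    // coupled asymmetric shortening, one Bernoulli per chromosome
    for (int j = 0; j < 16; ++j) {
      bool b = unif_rand() < 0.5;
      int l1 = Lbuf[2 * j], l2 = Lbuf[2 * j + 1];
      int hcut = (int)P.h;
      if (b) {
        d1[2 * j] = l1 - hcut;     d1[2 * j + 1] = l2;
        d2[2 * j] = l1;            d2[2 * j + 1] = l2 - hcut;
      } else {
        d1[2 * j] = l1;            d1[2 * j + 1] = l2 - hcut;
        d2[2 * j] = l1 - hcut;     d2[2 * j + 1] = l2;
      }
      if (d1[2 * j] < 0) d1[2 * j] = 0;
      if (d1[2 * j + 1] < 0) d1[2 * j + 1] = 0;
      if (d2[2 * j] < 0) d2[2 * j] = 0;
      if (d2[2 * j + 1] < 0) d2[2 * j + 1] = 0;
    }

    for (int which = 0; which < 2; ++which) {
      const int* dl = which == 0 ? d1 : d2;
      int lmin = dl[0];
      for (int j = 1; j < 32; ++j) if (dl[j] < lmin) lmin = dl[j];
      Fate f = next_fate(mT, mC, (double)lmin, P);
      if (f.onset) {
        onset_t.push_back(t); onset_ty.push_back(f.type);
        onset_l.push_back((double)lmin);
      }
      if (!f.alive) continue;
      double tau = draw_duration(pool_for(f.type, f.cyc, norA, norB, ntaD, senD));
      int slot;
      if (!freeSlots.empty()) {
        slot = freeSlots.back(); freeSlots.pop_back();
        for (int j = 0; j < 32; ++j) teloV[(size_t)32 * slot + j] = dl[j];
        typeV[slot] = f.type; cycV[slot] = f.cyc;
        genV[slot] = mG + 1; ancV[slot] = mA;
        timeV[slot] = t + tau; aliveV[slot] = 1;
      } else {
        slot = (int)typeV.size();
        for (int j = 0; j < 32; ++j) teloV.push_back(dl[j]);
        typeV.push_back(f.type); cycV.push_back(f.cyc);
        genV.push_back(mG + 1); ancV.push_back(mA);
        timeV.push_back(t + tau); aliveV.push_back(1);
      }
      heap.push(Ev(t + tau, slot));
      ++alive_count;
    }

    if (alive_count >= n_sat) { frozen = true; t_freeze = t; break; }
    if (alive_count == 0) break;
  }

  while (next_mark <= t_end) {
    hour_t.push_back(next_mark); hour_n.push_back(alive_count);
    next_mark += 60.0;
  }

  // collect the living cells
  IntegerMatrix out_telo(32, alive_count);
  IntegerVector out_type(alive_count), out_cyc(alive_count),
                out_gen(alive_count), out_anc(alive_count);
  NumericVector out_time(alive_count);
  int k = 0;
  for (int s = 0; s < (int)typeV.size(); ++s) {
    if (!aliveV[s]) continue;
    for (int j = 0; j < 32; ++j) out_telo(j, k) = teloV[(size_t)32 * s + j];
    out_type[k] = typeV[s]; out_cyc[k] = cycV[s];
    out_gen[k] = genV[s]; out_anc[k] = ancV[s];
    out_time[k] = timeV[s];
    ++k;
  }

  return List::create(
    _["telo"] = out_telo, _["type"] = out_type, _["cyc"] = out_cyc,
    _["gen"] = out_gen, _["anc"] = out_anc, _["div_time"] = out_time,
    _["frozen"] = frozen, _["t_freeze"] = t_freeze,
    _["n_divisions"] = (double)n_div,
    _["onset_time"] = NumericVector(onset_t.begin(), onset_t.end()),
    _["onset_type"] = IntegerVector(onset_ty.begin(), onset_ty.end()),
    _["onset_shortest"] = NumericVector(onset_l.begin(), onset_l.end()),
    _["hour_time"] = NumericVector(hour_t.begin(), hour_t.end()),
    _["hour_count"] = IntegerVector(hour_n.begin(), hour_n.end()));
}

// Batch single-lineage simulation (microfluidics setting): one daughter is
// tracked per division, chosen uniformly.  Returns per-lineage summaries;
// the observed classification uses only sampled durations and the long-
// cycle threshold D, like the experimental analysis.
// [[Rcpp::export]]
List cpp_simulate_lineages(IntegerMatrix founders, List params, List bank,
                           int max_gen) {
  const Params P = read_params(params);
  const NumericVector norA = bank["nor_A"], norB = bank["nor_B"],
                      ntaD = bank["nta"], senD = bank["sen"];
  if (founders.nrow() != 32) stop("cpp_simulate_lineages: founders must be 32 x n");
  const int n = founders.ncol();

  IntegerVector gen_first_nta(n), gen_sen(n), gen_death(n), death_cause(n),
                observed_type(n), sen_onset_l(n);
  LogicalVector is_M(n);

  int L[32], d1[32], d2[32];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 32; ++j) L[j] = founders(j, i);
    int type = 1, cyc = 1, gen = 0;
    int g_nta = -1, g_sen = -1, cause = 3, onset_l = -1;
    bool long_seen = false, observed_B = false, ever_nta = false;

    // generation-0 cycle
    double dur = draw_duration(pool_for(type, cyc, norA, norB, ntaD, senD));
    if (dur >= P.D) long_seen = true;

    while (gen < max_gen) {
      for (int j = 0; j < 16; ++j) {
        bool b = unif_rand() < 0.5;
        int l1 = L[2 * j], l2 = L[2 * j + 1];
        int hcut = (int)P.h;
        if (b) { d1[2*j] = l1 - hcut; d1[2*j+1] = l2;
                 d2[2*j] = l1;        d2[2*j+1] = l2 - hcut; }
        else   { d1[2*j] = l1;        d1[2*j+1] = l2 - hcut;
                 d2[2*j] = l1 - hcut; d2[2*j+1] = l2; }
      }
      const int* dl = unif_rand() < 0.5 ? d1 : d2;
      int lmin = 0;
      for (int j = 0; j < 32; ++j) {
        L[j] = dl[j] < 0 ? 0 : dl[j];
        if (j == 0 || L[j] < lmin) lmin = L[j];
      }
      Fate f = next_fate(type, cyc, (double)lmin, P);
      if (!f.alive) { cause = f.cause; break; }
      type = f.type; cyc = f.cyc;
      ++gen;
      if (cyc == 2) { ever_nta = true; if (g_nta < 0) g_nta = gen; }
      if (cyc == 3 && g_sen < 0) { g_sen = gen; onset_l = lmin; }
      dur = draw_duration(pool_for(type, cyc, norA, norB, ntaD, senD));
      if (dur >= P.D) long_seen = true;
      else if (long_seen) observed_B = true;
    }

    gen_first_nta[i] = g_nta; gen_sen[i] = g_sen; gen_death[i] = gen;
    death_cause[i] = cause;
    observed_type[i] = observed_B ? 2 : 1;
    is_M[i] = (!observed_B) && ever_nta;
    sen_onset_l[i] = onset_l;
  }

  return List::create(
    _["gen_first_nta"] = gen_first_nta, _["gen_sen"] = gen_sen,
    _["gen_death"] = gen_death, _["death_cause"] = death_cause,
    _["observed_type"] = observed_type, _["is_M"] = is_M,
    _["sen_onset_shortest"] = sen_onset_l);
}
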