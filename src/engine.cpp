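// Discrete-event core for shelterflow.
//
// A single replication is executed entirely in C++ over a binary-heap event
// calendar.  Simultaneous events are ordered
//   capacity_change < housing_stay_end < shelter_stay_end < arrival < sample_tick
// then by insertion sequence, so capacity present at an instant is usable by
// departures and arrivals at that instant.
//
// Randomness is counter-based: every person carries a 64-bit key derived
// deterministically from (master_seed, replication, arrival index) — or, for
// returners, from the parent's key — and all of that person's draws (pathway
// reassignment, service times, return decision and delay) come from a
// splitmix64 stream seeded by that key.  Arrival times come from a separate
// stream.  This gives byte-identical traces for identical inputs and tight
// common-random-number coupling across policies: person k's arrival time and
// service demands are unchanged when only capacity schedules differ.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <deque>
#include <queue>
#include <vector>

using namespace Rcpp;

namespace {

inline uint64_t splitmix(uint64_t& s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s;
  double u() { return (splitmix(s) >> 11) * (1.0 / 9007199254740992.0); }
};

inline uint64_t hash2(uint64_t a, uint64_t b) {
  uint64_t s = a ^ 0xD6E8FEB86659FD93ULL;
  splitmix(s);
  s ^= b * 0xC2B2AE3D27D4EB4FULL;
  splitmix(s);
  return splitmix(s);
}

// Distribution kinds: 0 triangular(min,mode,max), 1 uniform(min,max),
// 2 fixed(value), 3 exponential(mean).  All parameters in days.
double sample_dist(int kind, double p1, double p2, double p3, Rng& g) {
  switch (kind) {
  case 0: {
    double u = g.u(), fm = (p2 - p1) / (p3 - p1);
    if (u < fm) return p1 + std::sqrt(u * (p3 - p1) * (p2 - p1));
    return p3 - std::sqrt((1.0 - u) * (p3 - p1) * (p3 - p2));
  }
  case 1: return p1 + (p2 - p1) * g.u();
  case 2: return p1;
  case 3: return -p1 * std::log(1.0 - g.u());
  }
  stop("unknown distribution kind");
  return 0.0;  // not reached
}

// Stationary residual of a service time: the time left for an occupant
// observed at a random instant of a system in equilibrium.  Sampled as
// U * X~ with X~ length-biased (rejection against the support upper bound);
// the exponential kind is memoryless, so a full draw is its own residual.
double residual_draw(int kind, double p1, double p2, double p3, Rng& g) {
  if (kind == 3) return sample_dist(kind, p1, p2, p3, g);
  double ub = (kind == 0) ? p3 : (kind == 1) ? p2 : p1;
  if (ub <= 0.0) return 0.0;
  double x;
  do {
    x = sample_dist(kind, p1, p2, p3, g);
  } while (g.u() * ub > x);
  return g.u() * x;
}

// Piecewise-homogeneous Poisson process by exact per-segment exponential
// gaps: an Exp(1) hazard budget is spent across rate segments, so gaps are
// exact even when they straddle a rate change.
std::vector<double> gen_nhpp(const std::vector<double>& seg_start,
                             const std::vector<double>& rate,
                             double horizon, Rng& g) {
  std::vector<double> out;
  size_t k = 0;
  double t = 0.0;
  double E = -std::log(1.0 - g.u());
  while (true) {
    double seg_end = (k + 1 < seg_start.size()) ? seg_start[k + 1] : horizon;
    if (seg_end > horizon) seg_end = horizon;
    double cap = rate[k] * (seg_end - t);
    if (E > cap) {
      E -= cap;
      t = seg_end;
      if (k + 1 < seg_start.size() && seg_start[k + 1] < horizon) { ++k; continue; }
      break;
    }
    t += (rate[k] > 0.0) ? E / rate[k] : 0.0;
    if (t >= horizon) break;
    out.push_back(t);
    E = -std::log(1.0 - g.u());
  }
  return out;
}

enum EvKind { EV_CAP = 0, EV_HEND = 1, EV_SEND = 2, EV_ARR = 3, EV_RET = 4, EV_TICK = 5 };

inline int ev_pri(int kind) {
  switch (kind) {
  case EV_CAP:  return 0;
  case EV_HEND: return 1;
  case EV_SEND: return 2;
  case EV_ARR:  return 3;
  case EV_RET:  return 3;
  case EV_TICK: return 4;
  }
  return 9;
}

struct Ev {
  double t;
  int pri;
  long long seq;
  int kind;
  int a;     // person index, arrival index, or resource code (-1 = shelter)
  double x;  // capacity target for EV_CAP
};

struct EvCmp {
  bool operator()(const Ev& l, const Ev& r) const {
    if (l.t != r.t) return l.t > r.t;
    if (l.pri != r.pri) return l.pri > r.pri;
    return l.seq > r.seq;
  }
};

// Event-log kinds (exported codes)
enum LogKind { LG_CAP = 0, LG_HEND = 1, LG_SEND = 2, LG_ARR = 3, LG_RET = 4,
               LG_HADMIT = 5, LG_SADMIT = 6 };

struct Resource {
  int active = 0, occupied = 0, retiring = 0;
  std::deque<int> q_out;   // unsheltered waiters, FIFO by (arrival, seq)
  std::deque<int> q_shel;  // sheltered waiters, FIFO by (arrival, seq)
};

struct Sim {
  // configuration
  double horizon;
  int n_pw = 0, n_res = 0;
  std::vector<double> pw_cum;           // cumulative pathway mix
  std::vector<int> pw_policy;           // 0 none, 1 until_housing, 2 fixed_stay
  std::vector<int> pw_rank;             // dense shelter priority rank (0 best)
  std::vector<int> pw_res;              // housing resource index or -1
  std::vector<int> pw_stay_kind;
  std::vector<double> pw_stay_p1, pw_stay_p2, pw_stay_p3;
  std::vector<int> pw_house_kind;
  std::vector<double> pw_house_p1, pw_house_p2, pw_house_p3;
  std::vector<int> res_pw;              // pathway served by each resource
  double ret_prob = 0.0;
  int ret_kind = 1;
  double ret_p1 = 0.0, ret_p2 = 0.0, ret_p3 = 0.0;
  bool ret_reassign = true;
  int rule = 0;  // 0 fifo_overall, 1 shelter_first
  uint64_t svc_seed = 0, ext_key_base = 0;

  // state
  std::vector<Resource> res;
  Resource shel;
  std::vector<std::deque<int>> shelQ;  // one FIFO deque per priority rank
  std::priority_queue<Ev, std::vector<Ev>, EvCmp> heap;
  long long seq = 0;
  std::vector<int> n_queued, n_sheltered;
  int tot_q = 0, tot_s = 0;
  long long cum_arr = 0, cum_ret = 0, cum_exit = 0;
  double last_t = 0.0, int_queued = 0.0, int_unmet = 0.0;

  // person records
  std::vector<int> p_pw, p_state, p_isret;
  std::vector<double> p_arr, p_shein, p_sheout, p_hin, p_exit;
  std::vector<uint64_t> p_key, p_rng;

  // pre-generated external arrivals
  std::vector<double> arr_times;
  std::vector<int> arr_pw;

  // event log
  bool record = false;
  std::vector<double> lg_t;
  std::vector<int> lg_kind, lg_person, lg_res, lg_occ, lg_active;

  void log(double t, int kind, int person, int rescode, int occ, int active) {
    if (!record) return;
    lg_t.push_back(t);
    lg_kind.push_back(kind);
    lg_person.push_back(person);
    lg_res.push_back(rescode);
    lg_occ.push_back(occ);
    lg_active.push_back(active);
  }

  void push_ev(double t, int kind, int a, double x = 0.0) {
    if (t > horizon) return;
    heap.push(Ev{t, ev_pri(kind), seq++, kind, a, x});
  }

  void advance(double t) {
    double dt = t - last_t;
    if (dt > 0) {
      int_queued += tot_q * dt;
      int_unmet += (tot_q + tot_s) * dt;
      last_t = t;
    }
  }

  double person_draw_dist(int p, int kind, double a, double b, double c) {
    Rng g{p_rng[p]};
    double v = sample_dist(kind, a, b, c, g);
    p_rng[p] = g.s;
    return v;
  }

  double person_draw_residual(int p, int kind, double a, double b, double c) {
    Rng g{p_rng[p]};
    double v = residual_draw(kind, a, b, c, g);
    p_rng[p] = g.s;
    return v;
  }

  double person_u(int p) {
    Rng g{p_rng[p]};
    double v = g.u();
    p_rng[p] = g.s;
    return v;
  }

  int new_person(int pw, double t, bool is_ret, uint64_t key) {
    p_pw.push_back(pw);
    p_state.push_back(0);
    p_isret.push_back(is_ret ? 1 : 0);
    p_arr.push_back(t);
    p_shein.push_back(-1.0);
    p_sheout.push_back(-1.0);
    p_hin.push_back(-1.0);
    p_exit.push_back(-1.0);
    p_key.push_back(key);
    p_rng.push_back(hash2(svc_seed, key));
    return static_cast<int>(p_pw.size()) - 1;
  }

  int pick_pathway(double u) const {
    for (int i = 0; i < n_pw; ++i)
      if (u < pw_cum[i]) return i;
    return n_pw - 1;
  }

  void clean_out(Resource& R) {
    while (!R.q_out.empty() && p_state[R.q_out.front()] != 0) R.q_out.pop_front();
  }
  void clean_shel(Resource& R) {
    while (!R.q_shel.empty() && p_state[R.q_shel.front()] != 1) R.q_shel.pop_front();
  }

  // A shelter departure never recurses back into allocation: it only does
  // the retiring bookkeeping; the settle() fixed point re-runs admissions.
  void release_shelter(double t) {
    shel.occupied--;
    if (shel.retiring > 0) {
      shel.retiring--;
      shel.active--;
    }
  }

  void admit_housing(int p, int r, double t, bool from_shelter) {
    int pw = p_pw[p];
    p_state[p] = 2;
    p_hin[p] = t;
    res[r].occupied++;
    if (from_shelter) {
      n_sheltered[pw]--; tot_s--;
      p_sheout[p] = t;
    } else {
      n_queued[pw]--; tot_q--;
    }
    double dur = person_draw_dist(p, pw_house_kind[pw], pw_house_p1[pw],
                                  pw_house_p2[pw], pw_house_p3[pw]);
    push_ev(t + dur, EV_HEND, p);
    log(t, LG_HADMIT, p, r, res[r].occupied, res[r].active);
    if (from_shelter) release_shelter(t);
  }

  // Admission rules: 0 fifo_overall (earliest arrival across sheltered and
  // unsheltered waiters), 1 shelter_first (sheltered waiters preferred),
  // 2 shelter_transit (shelter-using pathways are housed only out of
  // shelter; housing never bypasses the shelter stage).
  bool try_house_pass(int r, double t) {
    Resource& R = res[r];
    bool progress = false;
    while (R.occupied < R.active) {
      clean_out(R);
      clean_shel(R);
      bool direct_pathway = pw_policy[res_pw[r]] == 0;
      bool has_o = !R.q_out.empty() && (rule != 2 || direct_pathway);
      bool has_s = !R.q_shel.empty();
      if (!has_o && !has_s) break;
      bool from_shel;
      if (rule == 1 || rule == 2) {
        from_shel = has_s;
      } else if (has_o && has_s) {
        int po = R.q_out.front(), ps = R.q_shel.front();
        from_shel = (p_arr[ps] < p_arr[po]) || (p_arr[ps] == p_arr[po] && ps < po);
      } else {
        from_shel = has_s;
      }
      int p;
      if (from_shel) { p = R.q_shel.front(); R.q_shel.pop_front(); }
      else           { p = R.q_out.front();  R.q_out.pop_front();  }
      admit_housing(p, r, t, from_shel);
      progress = true;
    }
    return progress;
  }

  bool try_shelter_pass(double t) {
    bool progress = false;
    while (shel.occupied < shel.active) {
      int p = -1;
      for (size_t rk = 0; rk < shelQ.size(); ++rk) {
        std::deque<int>& dq = shelQ[rk];
        while (!dq.empty() && p_state[dq.front()] != 0) dq.pop_front();
        if (!dq.empty()) { p = dq.front(); dq.pop_front(); break; }
      }
      if (p < 0) break;
      int pw = p_pw[p];
      p_state[p] = 1;
      p_shein[p] = t;
      n_queued[pw]--; tot_q--;
      n_sheltered[pw]++; tot_s++;
      shel.occupied++;
      if (pw_policy[pw] == 2) {
        double d = person_draw_dist(p, pw_stay_kind[pw], pw_stay_p1[pw],
                                    pw_stay_p2[pw], pw_stay_p3[pw]);
        push_ev(t + d, EV_SEND, p);
      } else {
        res[pw_res[pw]].q_shel.push_back(p);
      }
      log(t, LG_SADMIT, p, -1, shel.occupied, shel.active);
      progress = true;
    }
    return progress;
  }

  // Run admissions to a fixed point: a housing admission can free a shelter
  // unit, whose refill can in turn unblock a housing unit (shelter_transit),
  // so passes alternate until neither makes progress.
  void settle(double t) {
    bool again = true;
    while (again) {
      again = false;
      for (int r = 0; r < n_res; ++r)
        if (try_house_pass(r, t)) again = true;
      if (try_shelter_pass(t)) again = true;
    }
  }

  void set_target(int rescode, double t, int target) {
    Resource& R = (rescode < 0) ? shel : res[rescode];
    if (R.occupied <= target) {
      R.active = target;
      R.retiring = 0;
    } else {
      R.active = R.occupied;
      R.retiring = R.occupied - target;
    }
    log(t, LG_CAP, -1, rescode, R.occupied, R.active);
    settle(t);
  }

  void process_arrival(int p, double t) {
    int pw = p_pw[p];
    cum_arr++;
    if (p_isret[p]) cum_ret++;
    n_queued[pw]++; tot_q++;
    bool uses_housing = pw_res[pw] >= 0;
    if (uses_housing) res[pw_res[pw]].q_out.push_back(p);
    if (pw_policy[pw] != 0) shelQ[pw_rank[pw]].push_back(p);
    log(t, p_isret[p] ? LG_RET : LG_ARR, p, -2, tot_q, 0);
    settle(t);
  }

  void housing_end(int p, double t) {
    int pw = p_pw[p];
    int r = pw_res[pw];
    p_state[p] = 3;
    p_exit[p] = t;
    cum_exit++;
    res[r].occupied--;
    log(t, LG_HEND, p, r, res[r].occupied, res[r].active);
    if (res[r].retiring > 0) {
      res[r].retiring--;
      res[r].active--;
    } else {
      settle(t);
    }
    if (ret_prob > 0.0 && person_u(p) < ret_prob) {
      double d = person_draw_dist(p, ret_kind, ret_p1, ret_p2, ret_p3);
      push_ev(t + d, EV_RET, p);
    }
  }

  void shelter_end(int p, double t) {
    int pw = p_pw[p];
    p_state[p] = 3;
    p_exit[p] = t;
    p_sheout[p] = t;
    cum_exit++;
    n_sheltered[pw]--; tot_s--;
    log(t, LG_SEND, p, -1, shel.occupied - 1, shel.active);
    release_shelter(t);
    settle(t);
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_sample_duration(int kind, double p1, double p2, double p3,
                                  int n, double seed) {
  Rng g{hash2(static_cast<uint64_t>(seed), 0x5A11ULL)};
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_dist(kind, p1, p2, p3, g);
  return out;
}

// [[Rcpp::export]]
List cpp_generate_arrivals(NumericVector seg_start, NumericVector seg_rate,
                           double horizon, NumericVector pw_cum,
                           double master_seed, int rep_index) {
  uint64_t base = hash2(static_cast<uint64_t>(master_seed),
                        static_cast<uint64_t>(rep_index));
  Rng ga{hash2(base, 1)};
  Rng gp{hash2(base, 2)};
  std::vector<double> st(seg_start.begin(), seg_start.end());
  std::vector<double> rt(seg_rate.begin(), seg_rate.end());
  std::vector<double> times = gen_nhpp(st, rt, horizon, ga);
  int n = static_cast<int>(times.size());
  IntegerVector pw(n);
  int npw = pw_cum.size();
  for (int i = 0; i < n; ++i) {
    double u = gp.u();
    int k = npw - 1;
    for (int j = 0; j < npw; ++j)
      if (u < pw_cum[j]) { k = j; break; }
    pw[i] = k + 1;  // 1-based for R
  }
  return List::create(_["time"] = NumericVector(times.begin(), times.end()),
                      _["pathway"] = pw);
}

// [[Rcpp::export]]
List cpp_run_replication(List cfg, int rep_index, bool record_events) {
  Sim S;
  S.horizon = as<double>(cfg["horizon"]);
  S.record = record_events;

  NumericVector prop = cfg["pw_prop"];
  S.n_pw = prop.size();
  double acc = 0.0;
  for (int i = 0; i < S.n_pw; ++i) { acc += prop[i]; S.pw_cum.push_back(acc); }
  S.pw_cum[S.n_pw - 1] = 1.0 + 1e-12;

  S.pw_policy = as<std::vector<int>>(cfg["pw_policy"]);
  S.pw_rank = as<std::vector<int>>(cfg["pw_rank"]);
  S.pw_res = as<std::vector<int>>(cfg["pw_res"]);
  S.pw_stay_kind = as<std::vector<int>>(cfg["pw_stay_kind"]);
  S.pw_stay_p1 = as<std::vector<double>>(cfg["pw_stay_p1"]);
  S.pw_stay_p2 = as<std::vector<double>>(cfg["pw_stay_p2"]);
  S.pw_stay_p3 = as<std::vector<double>>(cfg["pw_stay_p3"]);
  S.pw_house_kind = as<std::vector<int>>(cfg["pw_house_kind"]);
  S.pw_house_p1 = as<std::vector<double>>(cfg["pw_house_p1"]);
  S.pw_house_p2 = as<std::vector<double>>(cfg["pw_house_p2"]);
  S.pw_house_p3 = as<std::vector<double>>(cfg["pw_house_p3"]);
  S.res_pw = as<std::vector<int>>(cfg["res_pw"]);
  S.n_res = static_cast<int>(S.res_pw.size());

  S.ret_prob = as<double>(cfg["ret_prob"]);
  S.ret_kind = as<int>(cfg["ret_kind"]);
  S.ret_p1 = as<double>(cfg["ret_p1"]);
  S.ret_p2 = as<double>(cfg["ret_p2"]);
  S.ret_p3 = as<double>(cfg["ret_p3"]);
  S.ret_reassign = as<bool>(cfg["ret_reassign"]);
  S.rule = as<int>(cfg["admission_rule"]);

  double master_seed = as<double>(cfg["master_seed"]);
  uint64_t base = hash2(static_cast<uint64_t>(master_seed),
                        static_cast<uint64_t>(rep_index));
  S.svc_seed = hash2(base, 4);
  S.ext_key_base = hash2(base, 3);

  int n_rank = as<int>(cfg["n_rank"]);
  S.shelQ.assign(n_rank, std::deque<int>());
  S.res.assign(S.n_res, Resource());
  S.n_queued.assign(S.n_pw, 0);
  S.n_sheltered.assign(S.n_pw, 0);

  // initial capacities
  S.shel.active = as<int>(cfg["shelter_init_cap"]);
  IntegerVector ric = cfg["res_init_cap"];
  for (int r = 0; r < S.n_res; ++r) S.res[r].active = ric[r];

  // external arrivals
  if (cfg.containsElementNamed("fixed_arr_times")) {
    NumericVector ft = cfg["fixed_arr_times"];
    IntegerVector fp = cfg["fixed_arr_pathway"];
    S.arr_times.assign(ft.begin(), ft.end());
    for (int i = 0; i < fp.size(); ++i) S.arr_pw.push_back(fp[i] - 1);
  } else {
    NumericVector st = cfg["arr_seg_start"], rt = cfg["arr_seg_rate"];
    Rng ga{hash2(base, 1)};
    Rng gp{hash2(base, 2)};
    std::vector<double> sst(st.begin(), st.end()), srt(rt.begin(), rt.end());
    S.arr_times = gen_nhpp(sst, srt, S.horizon, ga);
    for (size_t i = 0; i < S.arr_times.size(); ++i)
      S.arr_pw.push_back(S.pick_pathway(gp.u()));
  }

  // initial population: housed occupants, then sheltered, then queued, all at
  // t = 0, with fresh full service-time draws for occupants.
  IntegerVector ih = cfg["init_housing_occ"];  // per resource
  IntegerVector is = cfg["init_shelter_occ"];  // per pathway
  IntegerVector iq = cfg["init_queue"];        // per pathway
  int residual_rule = as<int>(cfg["residual_rule"]);  // 0 fresh, 1 stationary
  uint64_t init_key = hash2(base, 5);
  long long ic = 0;
  for (int r = 0; r < S.n_res; ++r) {
    int pw = S.res_pw[r];
    for (int k = 0; k < ih[r]; ++k) {
      int p = S.new_person(pw, 0.0, false, hash2(init_key, ic++));
      S.p_state[p] = 2;
      S.p_hin[p] = 0.0;
      S.res[r].occupied++;
      double dur = residual_rule == 1
        ? S.person_draw_residual(p, S.pw_house_kind[pw], S.pw_house_p1[pw],
                                 S.pw_house_p2[pw], S.pw_house_p3[pw])
        : S.person_draw_dist(p, S.pw_house_kind[pw], S.pw_house_p1[pw],
                             S.pw_house_p2[pw], S.pw_house_p3[pw]);
      S.push_ev(dur, EV_HEND, p);
      S.cum_arr++;
    }
    if (S.res[r].occupied > S.res[r].active)
      stop("initial housing occupancy exceeds capacity");
  }
  for (int pw = 0; pw < S.n_pw; ++pw) {
    for (int k = 0; k < is[pw]; ++k) {
      int p = S.new_person(pw, 0.0, false, hash2(init_key, ic++));
      S.p_state[p] = 1;
      S.p_shein[p] = 0.0;
      S.shel.occupied++;
      S.n_sheltered[pw]++; S.tot_s++;
      if (S.pw_policy[pw] == 2) {
        double d = residual_rule == 1
          ? S.person_draw_residual(p, S.pw_stay_kind[pw], S.pw_stay_p1[pw],
                                   S.pw_stay_p2[pw], S.pw_stay_p3[pw])
          : S.person_draw_dist(p, S.pw_stay_kind[pw], S.pw_stay_p1[pw],
                               S.pw_stay_p2[pw], S.pw_stay_p3[pw]);
        S.push_ev(d, EV_SEND, p);
      } else if (S.pw_res[pw] >= 0) {
        S.res[S.pw_res[pw]].q_shel.push_back(p);
      }
      S.cum_arr++;
    }
  }
  if (S.shel.occupied > S.shel.active)
    stop("initial shelter occupancy exceeds capacity");
  for (int pw = 0; pw < S.n_pw; ++pw) {
    for (int k = 0; k < iq[pw]; ++k) {
      int p = S.new_person(pw, 0.0, false, hash2(init_key, ic++));
      S.n_queued[pw]++; S.tot_q++;
      if (S.pw_res[pw] >= 0) S.res[S.pw_res[pw]].q_out.push_back(p);
      if (S.pw_policy[pw] != 0) S.shelQ[S.pw_rank[pw]].push_back(p);
      S.cum_arr++;
    }
  }
  // settle any initial slack
  S.settle(0.0);

  // schedule capacity changes, arrivals, sample ticks
  {
    NumericVector ct = cfg["shelter_cap_time"], cx = cfg["shelter_cap_target"];
    for (int i = 0; i < ct.size(); ++i) S.push_ev(ct[i], EV_CAP, -1, cx[i]);
    List rct = cfg["res_cap_time"], rcx = cfg["res_cap_target"];
    for (int r = 0; r < S.n_res; ++r) {
      NumericVector t1 = rct[r], x1 = rcx[r];
      for (int i = 0; i < t1.size(); ++i) S.push_ev(t1[i], EV_CAP, r, x1[i]);
    }
  }
  for (size_t i = 0; i < S.arr_times.size(); ++i)
    S.push_ev(S.arr_times[i], EV_ARR, static_cast<int>(i));
  NumericVector ticks = cfg["sample_times"];
  for (int i = 0; i < ticks.size(); ++i) S.push_ev(ticks[i], EV_TICK, i);

  // output series
  int nt = ticks.size();
  NumericVector o_shel(nt);
  NumericMatrix o_house(nt, S.n_res), o_queued(nt, S.n_pw), o_shelt(nt, S.n_pw);
  NumericVector o_cumarr(nt), o_cumret(nt), o_cumexit(nt);

  // main loop
  while (!S.heap.empty()) {
    Ev ev = S.heap.top();
    S.heap.pop();
    S.advance(ev.t);
    switch (ev.kind) {
    case EV_CAP:
      S.set_target(ev.a, ev.t, static_cast<int>(ev.x + 0.5));
      break;
    case EV_HEND:
      S.housing_end(ev.a, ev.t);
      break;
    case EV_SEND:
      S.shelter_end(ev.a, ev.t);
      break;
    case EV_ARR: {
      int idx = ev.a;
      int p = S.new_person(S.arr_pw[idx], ev.t, false,
                           hash2(S.ext_key_base, idx));
      S.process_arrival(p, ev.t);
      break;
    }
    case EV_RET: {
      int parent = ev.a;
      uint64_t key = hash2(S.p_key[parent], 0x9E37ULL);
      int p = S.new_person(0, ev.t, true, key);
      int pw = S.ret_reassign ? S.pick_pathway(S.person_u(p))
                              : S.p_pw[parent];
      S.p_pw[p] = pw;
      S.process_arrival(p, ev.t);
      break;
    }
    case EV_TICK: {
      int i = ev.a;
      o_shel[i] = S.shel.occupied;
      for (int r = 0; r < S.n_res; ++r) o_house(i, r) = S.res[r].occupied;
      for (int pw = 0; pw < S.n_pw; ++pw) {
        o_queued(i, pw) = S.n_queued[pw];
        o_shelt(i, pw) = S.n_sheltered[pw];
      }
      o_cumarr[i] = static_cast<double>(S.cum_arr);
      o_cumret[i] = static_cast<double>(S.cum_ret);
      o_cumexit[i] = static_cast<double>(S.cum_exit);
      break;
    }
    }
    // occupancy-bound invariant, checked at every event
    if (S.shel.occupied > S.shel.active)
      stop("invariant breach: shelter occupied > active at t=%f", ev.t);
    for (int r = 0; r < S.n_res; ++r)
      if (S.res[r].occupied > S.res[r].active)
        stop("invariant breach: housing occupied > active (resource %d) at t=%f",
             r + 1, ev.t);
  }

  // persons table
  int np = static_cast<int>(S.p_pw.size());
  IntegerVector q_pw(np), q_state(np), q_isret(np);
  NumericVector q_arr(np), q_shein(np), q_sheout(np), q_hin(np), q_exit(np);
  for (int i = 0; i < np; ++i) {
    q_pw[i] = S.p_pw[i] + 1;
    q_state[i] = S.p_state[i];
    q_isret[i] = S.p_isret[i];
    q_arr[i] = S.p_arr[i];
    q_shein[i] = S.p_shein[i] < 0 ? NA_REAL : S.p_shein[i];
    q_sheout[i] = S.p_sheout[i] < 0 ? NA_REAL : S.p_sheout[i];
    q_hin[i] = S.p_hin[i] < 0 ? NA_REAL : S.p_hin[i];
    q_exit[i] = S.p_exit[i] < 0 ? NA_REAL : S.p_exit[i];
  }

  List persons = List::create(
      _["pathway"] = q_pw, _["is_return"] = q_isret, _["arrival"] = q_arr,
      _["shelter_entry"] = q_shein, _["shelter_exit"] = q_sheout,
      _["housing_entry"] = q_hin, _["exit"] = q_exit, _["state"] = q_state);

  List out = List::create(
      _["times"] = ticks, _["shelter_occupied"] = o_shel,
      _["housing_occupied"] = o_house, _["queued"] = o_queued,
      _["sheltered"] = o_shelt, _["cum_arrivals"] = o_cumarr,
      _["cum_returns"] = o_cumret, _["cum_exits"] = o_cumexit,
      _["int_queued_persondays"] = S.int_queued,
      _["int_unmet_persondays"] = S.int_unmet,
      _["persons"] = persons);

  if (record_events) {
    out["events"] = List::create(
        _["time"] = NumericVector(S.lg_t.begin(), S.lg_t.end()),
        _["kind"] = IntegerVector(S.lg_kind.begin(), S.lg_kind.end()),
        _["person"] = IntegerVector(S.lg_person.begin(), S.lg_person.end()),
        _["resource"] = IntegerVector(S.lg_res.begin(), S.lg_res.end()),
        _["occupied_after"] = IntegerVector(S.lg_occ.begin(), S.lg_occ.end()),
        _["active_after"] = IntegerVector(S.lg_active.begin(), S.lg_active.end()));
  }
  return out;
}
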