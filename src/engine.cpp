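// Event-calendar core of the ED patient-flow simulator.
//
// All randomness lives in R: the engine receives pre-sampled, policy-
// independent patient attributes (arrival time, triage level, both consult
// durations, exam requirement vector) and is fully deterministic, which
// makes common random numbers across policies exact by construction.
//
// Shift model: each shift is staffed by its own crew. At a shift boundary
// the incoming crew is fully available; outgoing physicians still in
// consultation finish their current patient and then withdraw (services
// are never preempted).
//
// Event tie-breaking at equal times: consult_end < exam_end < report_ready
// < shift_change < arrival, then insertion order. A freed physician is
// therefore available to a same-instant arrival, and a capacity change is
// seen by an arrival at the shift boundary.

#include <Rcpp.h>
#include <deque>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {

enum EvType { CONSULT_END = 0, EXAM_END = 1, REPORT_READY = 2,
              SHIFT_CHANGE = 3, ARRIVAL = 4 };

struct Ev {
  double t;
  int type;
  long long seq;
  int a;  // patient (or shift-event index)
  int b;  // consult kind (1/2) or modality index
};

struct EvCmp {
  bool operator()(const Ev& x, const Ev& y) const {
    if (x.t != y.t) return x.t > y.t;
    if (x.type != y.type) return x.type > y.type;
    return x.seq > y.seq;
  }
};

struct Engine {
  // inputs
  const NumericVector& arr;
  const IntegerVector& level;
  const NumericVector& d1;
  const NumericVector& d2;
  const IntegerMatrix& exam;      // n x 4, 0/1
  const IntegerVector& ord;      // modality scheduling priority, 0-based
  const NumericVector& tau;
  const NumericVector& delta;
  const IntegerVector& cap;
  double horizon;
  int policy;                     // 0 IFP, 1 ALT, 2 SBP
  double T3, T4, k1, k2;

  // state
  std::priority_queue<Ev, std::vector<Ev>, EvCmp> cal;
  long long seq = 0;
  int R_cur = 0;                  // physicians of the current shift
  int busy = 0;                   // current-shift physicians in consultation
  int lame = 0;                   // outgoing-shift physicians finishing up
  double last_handover = -1.0;
  std::deque<int> q3, q4, qf;
  std::vector<int> dev_busy_units;
  std::vector<std::deque<int>> devq;
  std::vector<int> next_pos;      // index into ord of exam in progress
  std::vector<double> texam_max;

  // outputs
  NumericVector init_start, init_end, t_exam, fu_start, fu_end;
  NumericMatrix exam_start;
  double doc_busy = 0.0;
  std::vector<double> dev_busy_min;

  Engine(const NumericVector& arr_, const IntegerVector& level_,
         const NumericVector& d1_, const NumericVector& d2_,
         const IntegerMatrix& exam_, const IntegerVector& ord_,
         const NumericVector& tau_, const NumericVector& delta_,
         const IntegerVector& cap_, double horizon_, int policy_,
         double T3_, double T4_, double k1_, double k2_)
      : arr(arr_), level(level_), d1(d1_), d2(d2_), exam(exam_), ord(ord_),
        tau(tau_), delta(delta_), cap(cap_), horizon(horizon_),
        policy(policy_), T3(T3_), T4(T4_), k1(k1_), k2(k2_),
        dev_busy_units(4, 0), devq(4),
        next_pos(arr_.size(), -1), texam_max(arr_.size(), 0.0),
        init_start(arr_.size(), NA_REAL), init_end(arr_.size(), NA_REAL),
        t_exam(arr_.size(), NA_REAL), fu_start(arr_.size(), NA_REAL),
        fu_end(arr_.size(), NA_REAL),
        exam_start(arr_.size() == 0 ? 1 : (int)arr_.size(), 4),
        dev_busy_min(4, 0.0) {
    std::fill(exam_start.begin(), exam_start.end(), NA_REAL);
  }

  void push(double t, int type, int a, int b) {
    cal.push(Ev{t, type, seq++, a, b});
  }

  void start_consult(int p, int kind, double t) {
    ++busy;
    double dur = (kind == 1) ? d1[p] : d2[p];
    if (kind == 1) init_start[p] = t; else fu_start[p] = t;
    doc_busy += std::min(t + dur, horizon) - t;
    push(t + dur, CONSULT_END, p, kind);
  }

  void start_exam(int p, int j, double t) {
    ++dev_busy_units[j];
    exam_start(p, j) = t;
    dev_busy_min[j] += std::min(t + tau[j], horizon) - t;
    double report = t + tau[j] + delta[j];
    if (report > texam_max[p]) texam_max[p] = report;
    push(t + tau[j], EXAM_END, p, j);
  }

  void request_device(int p, int j, double t) {
    if (dev_busy_units[j] < cap[j]) start_exam(p, j, t);
    else devq[j].push_back(p);
  }

  int next_required(int p, int from) {
    for (int k = from; k < 4; ++k)
      if (exam(p, ord[k]) == 1) return k;
    return -1;
  }

  void on_consult_end(int p, int kind, double t) {
    double started = (kind == 1) ? init_start[p] : fu_start[p];
    if (lame > 0 && started < last_handover) --lame;  // outgoing crew leaves
    else --busy;
    if (kind == 2) { fu_end[p] = t; return; }
    init_end[p] = t;
    int pos = next_required(p, 0);
    if (pos >= 0) {
      next_pos[p] = pos;
      request_device(p, ord[pos], t);
    }
    // no exams: patient exits after the initial consult
  }

  void on_exam_end(int p, int j, double t) {
    --dev_busy_units[j];
    if (!devq[j].empty()) {
      int p2 = devq[j].front();
      devq[j].pop_front();
      start_exam(p2, j, t);
    }
    // the patient is free once processing ends; the report is produced
    // concurrently with any later exams
    int pos = next_required(p, next_pos[p] + 1);
    if (pos >= 0) {
      next_pos[p] = pos;
      request_device(p, ord[pos], t);
    } else {
      push(texam_max[p], REPORT_READY, p, 0);
    }
  }

  bool head_urgent3(double t) {
    return !q3.empty() && t - arr[q3.front()] >= T3 - k1;
  }
  bool head_urgent4(double t) {
    return !q4.empty() && t - arr[q4.front()] >= T4 - k2;
  }

  void pop_start(std::deque<int>& q, int kind, double t) {
    int p = q.front(); q.pop_front();
    start_consult(p, kind, t);
  }

  void allocate(double t) {
    int free = R_cur - busy;
    if (free <= 0) return;
    if (policy == 1) {
      // ALT: at most floor(free/2) physicians to initial consultations
      // (L3 before L4), remainder to follow-up; quota a category cannot
      // use is redistributed to the other.
      int D3 = q3.size(), D4 = q4.size(), Df = qf.size();
      if (D3 + D4 + Df == 0) return;
      int quota = free / 2;
      int n3 = std::min(D3, quota);
      int n4 = std::min(D4, quota - n3);
      int nf = std::min(Df, free - n3 - n4);
      int rem = free - n3 - n4 - nf;
      int e3 = std::min(D3 - n3, rem); n3 += e3; rem -= e3;
      n4 += std::min(D4 - n4, rem);
      for (int i = 0; i < n3; ++i) pop_start(q3, 1, t);
      for (int i = 0; i < n4; ++i) pop_start(q4, 1, t);
      for (int i = 0; i < nf; ++i) pop_start(qf, 2, t);
      return;
    }
    while (free > 0) {
      if (policy == 0) {  // IFP: L3 > L4 > follow-up
        if (!q3.empty()) pop_start(q3, 1, t);
        else if (!q4.empty()) pop_start(q4, 1, t);
        else if (!qf.empty()) pop_start(qf, 2, t);
        else break;
      } else {            // SBP: U3 > U4 > follow-up > non-urgent initial
        if (head_urgent3(t)) pop_start(q3, 1, t);
        else if (head_urgent4(t)) pop_start(q4, 1, t);
        else if (!qf.empty()) pop_start(qf, 2, t);
        else if (!q3.empty()) pop_start(q3, 1, t);
        else if (!q4.empty()) pop_start(q4, 1, t);
        else break;
      }
      --free;
    }
  }

  List run(const NumericVector& shift_time, const IntegerVector& shift_count) {
    int n = arr.size();
    for (int i = 0; i < n; ++i) push(arr[i], ARRIVAL, i, 0);
    for (int s = 0; s < shift_time.size(); ++s)
      push(shift_time[s], SHIFT_CHANGE, s, 0);
    while (!cal.empty()) {
      Ev e = cal.top();
      if (e.t >= horizon) break;
      cal.pop();
      switch (e.type) {
        case ARRIVAL:
          (level[e.a] == 3 ? q3 : q4).push_back(e.a);
          break;
        case CONSULT_END:
          on_consult_end(e.a, e.b, e.t);
          break;
        case EXAM_END:
          on_exam_end(e.a, e.b, e.t);
          break;
        case REPORT_READY:
          t_exam[e.a] = e.t;
          qf.push_back(e.a);
          break;
        case SHIFT_CHANGE:
          if (e.t > 0) {          // crew handover
            lame += busy;
            busy = 0;
            last_handover = e.t;
          }
          R_cur = shift_count[e.a];
          break;
      }
      allocate(e.t);
    }
    return List::create(
        _["init_start"] = init_start, _["init_end"] = init_end,
        _["t_exam"] = t_exam, _["fu_start"] = fu_start,
        _["fu_end"] = fu_end, _["exam_start"] = exam_start,
        _["doc_busy"] = doc_busy,
        _["dev_busy"] = NumericVector(dev_busy_min.begin(), dev_busy_min.end()),
        _["q3_end"] = (int)q3.size(), _["q4_end"] = (int)q4.size(),
        _["qf_end"] = (int)qf.size());
  }
};

}  // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericVector arr, IntegerVector level, NumericVector d1,
                NumericVector d2, IntegerMatrix exam, IntegerVector ord,
                NumericVector tau, NumericVector delta, IntegerVector cap,
                NumericVector shift_time, IntegerVector shift_count,
                double horizon, int policy, double T3, double T4,
                double k1, double k2) {
  Engine eng(arr, level, d1, d2, exam, ord, tau, delta, cap, horizon, policy,
             T3, T4, k1, k2);
  return eng.run(shift_time, shift_count);
}
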