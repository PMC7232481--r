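#include <Rcpp.h>
using namespace Rcpp;

// Minute-resolution COD-pool core of the synthetic digester.
//
// Pools (g COD in the reactor): S fast fermentable, D slow degradable,
// A acetate, P propionate, B butyrate, H hydrogen/formate equivalents,
// I inert. Consumption steps are zero-order (capacity-limited, clamped at
// the pool content), which reproduces the cascade-shaped daily methane rate
// curves: piecewise-constant rates with abrupt transitions as each pool
// empties. The propionate-oxidation and hydrogen-disposal capacities are
// multiplied by the per-day trace-element limitation factors facP/facH;
// propionate oxidation (and butyrate oxidation) is additionally inhibited
// by accumulated hydrogen, acetoclastic methanogenesis by propionate.
//
// Every transferred gram of COD lands in exactly one sink (CH4, biomass,
// effluent or a pool), so the daily ledger balances to floating-point
// accuracy. All sensor noise is added later, in R, on the measured outputs.
//
// [[Rcpp::export(name = ".simCoreCpp")]]
List simCore(int nDays, List pr, NumericVector facP, NumericVector facH) {
  const double hrt = pr["hrt"];
  const double vol = pr["volume"];
  const double feedDaily = pr["feedDaily"];   // g COD per day
  const double fFerm = pr["fFerm"], fAc = pr["fAc"], fPr = pr["fPr"],
               fSlow = pr["fSlow"], fInert = pr["fInert"];
  const double shareA = pr["shareA"], shareP = pr["shareP"], shareH = pr["shareH"];
  const double bShiftMax = pr["bShiftMax"], bShiftK = pr["bShiftK"]; // mM
  const double yF = pr["yF"], yP = pr["yP"], yB = pr["yB"],
               yA = pr["yA"], yH = pr["yH"];
  const double vS = pr["vS"], vA = pr["vA"], vP = pr["vP"],
               vH = pr["vH"], vB = pr["vB"];                 // g COD / min
  const double kSlowPerDay = pr["kSlowPerDay"];
  const double kiP = pr["kiP"];   // mM propionate, acetoclastic inhibition
  const double kiH = pr["kiH"];   // g COD / L hydrogen, syntrophy inhibition
  const double splitPA = pr["splitPA"], splitBA = pr["splitBA"];
  const double co2Meth = pr["co2Meth"], co2Ferm = pr["co2Ferm"];
  const double codA = 0.064, codP = 0.112, codB = 0.160;     // g COD / mmol
  const double mlPerG = 22414.0 / 64.0;                      // mL CH4 / g COD
  const double kSlowMin = kSlowPerDay / 1440.0;
  const double tol = 1e-9;

  double S = as<double>(pr["initS"]), D = as<double>(pr["initD"]),
         A = as<double>(pr["initA"]), P = as<double>(pr["initP"]),
         B = as<double>(pr["initB"]), H = as<double>(pr["initH"]),
         I = as<double>(pr["initI"]);

  const int nMin = nDays * 1440;
  NumericVector ch4Vol(nMin), co2Vol(nMin);
  NumericVector fedDay(nDays), efflDay(nDays), bioDay(nDays), ch4Day(nDays),
                invEnd(nDays), invStart(nDays), tResid(nDays);
  NumericVector preA(nDays), preP(nDays), preB(nDays), preH(nDays);
  // intra-day VFA snapshots every 180 min (8 per day), mM
  NumericMatrix snapA(nDays, 8), snapP(nDays, 8), snapB(nDays, 8);

  for (int d = 0; d < nDays; ++d) {
    // pre-feed residuals (mM; H as g/L)
    preA[d] = A / (vol * codA);
    preP[d] = P / (vol * codP);
    preB[d] = B / (vol * codB);
    preH[d] = H / vol;
    invStart[d] = S + D + A + P + B + H + I;

    // sludge withdrawal then feed addition (daily exchange of V/HRT)
    double w = 1.0 / hrt;
    double removed = (S + D + A + P + B + H + I) * w;
    S *= (1 - w); D *= (1 - w); A *= (1 - w); P *= (1 - w);
    B *= (1 - w); H *= (1 - w); I *= (1 - w);
    S += fFerm * feedDaily; A += fAc * feedDaily; P += fPr * feedDaily;
    D += fSlow * feedDaily; I += fInert * feedDaily;
    fedDay[d] = feedDaily;
    efflDay[d] = removed;

    double bio = 0.0, ch4 = 0.0;
    double fP = facP[d], fH = facH[d];
    int lastActive = 0;

    for (int m = 0; m < 1440; ++m) {
      // fermentation of fast and slow substrate
      double fermS = std::min(vS, S); S -= fermS;
      double fermD = kSlowMin * D;    D -= fermD;
      double ferm = fermS + fermD;
      bio += yF * ferm;
      double prod = (1 - yF) * ferm;
      double aMM = A / (vol * codA);
      double shiftB = bShiftMax * aMM / (aMM + bShiftK);
      A += prod * (shareA - shiftB);
      P += prod * shareP;
      H += prod * shareH;
      B += prod * shiftB;

      double hinh = 1.0 / (1.0 + (H / vol) / kiH);

      // syntrophic propionate oxidation (TE-limited, H2-inhibited)
      double consP = std::min(vP * fP * hinh, P); P -= consP;
      bio += yP * consP;
      A += consP * (1 - yP) * splitPA;
      H += consP * (1 - yP) * (1 - splitPA);

      // syntrophic butyrate oxidation
      double consB = std::min(vB * fH * hinh, B); B -= consB;
      bio += yB * consB;
      A += consB * (1 - yB) * splitBA;
      H += consB * (1 - yB) * (1 - splitBA);

      // acetoclastic methanogenesis (propionate-inhibited)
      double pMM = P / (vol * codP);
      double pinh = 1.0 / (1.0 + pMM / kiP);
      double consA = std::min(vA * pinh, A); A -= consA;
      bio += yA * consA;
      double ch4A = consA * (1 - yA);

      // hydrogenotrophic methanogenesis (TE-limited)
      double consH = std::min(vH * fH, H); H -= consH;
      bio += yH * consH;
      double ch4H = consH * (1 - yH);

      double ch4g = ch4A + ch4H;
      ch4 += ch4g;
      int idx = d * 1440 + m;
      ch4Vol[idx] = ch4g * mlPerG;
      co2Vol[idx] = co2Meth * ch4Vol[idx] + co2Ferm * ferm * mlPerG;

      if (A > tol || P > tol || B > tol || H > tol) lastActive = m + 1;
      if ((m + 1) % 180 == 0) {
        int s = (m + 1) / 180 - 1;
        snapA(d, s) = A / (vol * codA);
        snapP(d, s) = P / (vol * codP);
        snapB(d, s) = B / (vol * codB);
      }
    }
    bioDay[d] = bio;
    ch4Day[d] = ch4;
    invEnd[d] = S + D + A + P + B + H + I;
    tResid[d] = lastActive;
  }

  return List::create(
    _["ch4Vol"] = ch4Vol, _["co2Vol"] = co2Vol,
    _["fed"] = fedDay, _["effluent"] = efflDay, _["biomass"] = bioDay,
    _["ch4Cod"] = ch4Day, _["invStart"] = invStart, _["invEnd"] = invEnd,
    _["tResid"] = tResid,
    _["preA"] = preA, _["preP"] = preP, _["preB"] = preB, _["preH"] = preH,
    _["snapA"] = snapA, _["snapP"] = snapP, _["snapB"] = snapB
  );
}
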