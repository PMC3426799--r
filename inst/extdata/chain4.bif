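network chain4 {
}
variable X1 {
  type discrete [ 2 ] { s1, s2 };
}
variable X2 {
  type discrete [ 2 ] { s1, s2 };
}
variable X3 {
  type discrete [ 2 ] { s1, s2 };
}
variable X4 {
  type discrete [ 2 ] { s1, s2 };
}
probability ( X1 ) {
  table 0.5, 0.5;
}
probability ( X2 | X1 ) {
  ( s1 ) 0.90000000000000002, 0.10000000000000001;
  ( s2 ) 0.10000000000000001, 0.90000000000000002;
}
probability ( X3 | X2 ) {
  ( s1 ) 0.90000000000000002, 0.10000000000000001;
  ( s2 ) 0.10000000000000001, 0.90000000000000002;
}
probability ( X4 | X3 ) {
  ( s1 ) 0.90000000000000002, 0.10000000000000001;
  ( s2 ) 0.10000000000000001, 0.90000000000000002;
}
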