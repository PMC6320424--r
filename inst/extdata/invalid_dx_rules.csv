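sex,prefix
male,628
male,630
male,631
male,632
male,633
male,634
male,635
male,636
male,637
male,638
male,639
male,640
male,641
male,642
male,643
male,644
male,645
male,646
male,647
male,648
male,649
male,650
male,651
male,652
male,653
male,654
male,655
male,656
male,657
male,658
male,659
male,660
male,661
male,662
male,663
male,664
male,665
male,666
male,667
male,668
male,669
male,670
male,671
male,672
male,673
male,674
male,675
male,676
male,677
male,678
male,679
male,V22
male,V23
male,V27
male,V28
female,185
female,600
female,601
female,602
female,603
female,604
female,605
female,606
female,607
female,608
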